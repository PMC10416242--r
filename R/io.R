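# Readers and writers for the interchange formats: abundance TSV (QIIME
# dialect, taxa in rows) and BIOM, two-column taxonomy TSV with
# semicolon-joined SILVA-style lineages, edge-list TSV and GraphML.

#' Read an abundance table
#'
#' TSV tables are auto-oriented: a first header cell `#OTU ID` signals the
#' QIIME dialect (taxa in rows, samples in columns); otherwise rows are
#' taken as samples unless `orientation` says otherwise. Tables are
#' normalized internally to samples-by-taxa. BIOM files (JSON dialect) are
#' read through the biomformat package.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @param orientation `"auto"`, `"taxa_rows"` or `"samples_rows"`.
#' @return Abundance tibble (`sample_id` + one numeric column per taxon).
#' @export
read_abundance <- function(path, format = c("auto", "tsv", "biom"),
                           orientation = c("auto", "taxa_rows", "samples_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
    m <- t(m)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    prob <- readr::problems(df)
    if (nrow(prob)) abort(paste("malformed TSV:", path))
    first <- names(df)[1]
    taxa_rows <- if (orientation == "auto") identical(first, "#OTU ID")
                 else orientation == "taxa_rows"
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      abort(paste("duplicate identifiers:",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    m <- as.matrix(df[-1])
    if (!is.numeric(m)) abort("abundance values must be numeric")
    rownames(m) <- ids
    if (taxa_rows) m <- t(m)
  }
  if (anyDuplicated(colnames(m))) {
    abort(paste("duplicate taxon ids:",
                paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  }
  check_counts(m)
  abundance_tibble(m)
}

#' Write an abundance table
#'
#' TSV output uses the QIIME dialect: taxa in rows, a `#OTU ID` first
#' column, samples as remaining columns. BIOM output (JSON dialect) goes
#' through biomformat.
#'
#' @param table Abundance tibble or matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  m <- abundance_matrix(table)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("writing BIOM requires the biomformat package")
    }
    biomformat::write_biom(biomformat::make_biom(t(m)), path)
  } else {
    out <- dplyr::bind_cols(tibble(`#OTU ID` = colnames(m)),
                            as_tibble(t(m)))
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Read taxonomy from two-column TSV
#'
#' Expects columns `taxon_id` and a semicolon-joined lineage with optional
#' QIIME rank prefixes (`d__`, `p__`, ...). Missing trailing ranks are
#' padded with the empty label, which [relabel_mdm()] treats as unassigned.
#'
#' @param path File path.
#' @return Taxonomy tibble (`taxon_id` + seven rank columns).
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_names = c("taxon_id", "lineage"), skip = 1)
  parts <- stringr::str_split(df$lineage, ";")
  ranks <- tax_ranks()
  lab <- t(vapply(parts, function(p) {
    p <- stringr::str_trim(p)
    p <- stringr::str_replace(p, "^[dpcofgs]__", "")
    length(p) <- 7
    p[is.na(p)] <- ""
    p
  }, character(7)))
  colnames(lab) <- ranks
  dplyr::bind_cols(tibble(taxon_id = df$taxon_id), as_tibble(lab))
}

#' Write taxonomy as two-column TSV
#'
#' Lineages are joined with semicolons and carry QIIME rank prefixes.
#'
#' @param taxonomy Taxonomy tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  ranks <- tax_ranks()
  lab <- as.matrix(taxonomy[ranks])
  pref <- rank_prefixes()
  lineage <- apply(lab, 1, function(row) {
    paste(paste0(pref, row), collapse = ";")
  })
  readr::write_tsv(tibble(taxon_id = taxonomy$taxon_id, lineage = lineage),
                   path, progress = FALSE)
  invisible(path)
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param network An `mdm_network`.
#' @param path Output path for the 3-column edge list (`node_i`, `node_j`,
#'   `sign`).
#' @param graphml Optional path for a GraphML copy.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, graphml = NULL) {
  e <- network$edges
  readr::write_tsv(tibble(node_i = e$from, node_j = e$to,
                          sign = if ("sign" %in% names(e)) e$sign else rep(1, nrow(e))),
                   path, progress = FALSE)
  if (!is.null(graphml)) {
    igraph::write_graph(network_igraph(network), graphml, format = "graphml")
  }
  invisible(path)
}

#' Write edge bootstrap supports as TSV
#'
#' @param supports Tibble from [bootstrap_edge_support()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_support <- function(supports, path) {
  readr::write_tsv(tibble(node_i = supports$from, node_j = supports$to,
                          count = supports$bootstrap_count,
                          retained = supports$retained),
                   path, progress = FALSE)
  invisible(path)
}
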