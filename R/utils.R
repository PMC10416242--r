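# Shared internal helpers: abundance-table coercion, edge bookkeeping, seeding.

#' The seven taxonomic ranks, highest to lowest
#'
#' @return Character vector `c("domain", ..., "species")`.
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

# QIIME2/SILVA-style rank prefixes, in rank order
rank_prefixes <- function() {
  c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
}

#' Coerce an abundance tibble to a samples-by-taxa count matrix
#'
#' Abundance tables travel through the package as tibbles whose first column,
#' `sample_id`, identifies the sample and whose remaining numeric columns are
#' per-taxon counts. This helper converts to the matrix form used internally.
#'
#' @param table Abundance tibble (`sample_id` + one numeric column per taxon),
#'   or a numeric matrix with sample rownames, which is passed through.
#' @return Numeric matrix, samples in rows, taxa in columns.
#' @export
abundance_matrix <- function(table) {
  if (is.matrix(table)) {
    storage.mode(table) <- "double"
    return(table)
  }
  stopifnot(is.data.frame(table))
  if (!"sample_id" %in% names(table)) {
    abort("abundance table must have a `sample_id` column")
  }
  taxa <- setdiff(names(table), "sample_id")
  m <- as.matrix(table[taxa])
  if (!is.numeric(m)) abort("abundance columns must be numeric")
  rownames(m) <- as.character(table$sample_id)
  m
}

#' Build an abundance tibble from a samples-by-taxa matrix
#'
#' Inverse of [abundance_matrix()].
#'
#' @param m Numeric matrix, samples in rows (rownames = sample ids), taxa in
#'   columns (colnames = taxon ids).
#' @return Abundance tibble with `sample_id` first.
#' @export
abundance_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  ids <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  dplyr::bind_cols(tibble(sample_id = ids), as_tibble(m))
}

# Validate counts: non-negative, finite
check_counts <- function(m, what = "abundance table") {
  if (any(!is.finite(m))) abort(paste0(what, " contains non-finite values"))
  if (any(m < 0)) abort(paste0(what, " contains negative values"))
  invisible(m)
}

# Canonical edge tibble: from/to ordered by position in `nodes`
canonical_edges <- function(from, to, nodes, sign = NULL) {
  i <- match(from, nodes)
  j <- match(to, nodes)
  if (anyNA(i) || anyNA(j)) abort("edge endpoints not found in node set")
  swap <- i > j
  f <- ifelse(swap, nodes[j], nodes[i])
  t <- ifelse(swap, nodes[i], nodes[j])
  out <- tibble(from = f, to = t)
  if (!is.null(sign)) out$sign <- sign
  ord <- order(match(out$from, nodes), match(out$to, nodes))
  out <- out[ord, , drop = FALSE]
  dplyr::distinct(out, .data$from, .data$to, .keep_all = TRUE)
}

edge_key <- function(edges) paste(edges$from, edges$to, sep = "\r")

# Run `expr` under a temporary RNG seed when `seed` is non-NULL
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Counter-derived child seed, kept inside 32-bit integer range
child_seed <- function(seed, counter) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 1009 * as.double(counter)) %% .Machine$integer.max)
}
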