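# Microbial-dark-matter relabeling, prevalence/lineage filtering, rank
# aggregation, and cross-dataset classification comparison.

#' Default unknown-classification keyword set
#'
#' Keywords whose presence in a rank label marks a taxon as "microbial dark
#' matter" (MDM) at that rank. Reference taxonomies flag unknowns with a
#' non-exhaustive vocabulary, so the set is user-extensible: pass additions
#' via `extra`. `"NA"` and the empty label are matched as whole labels (as a
#' substring, "na" would falsely flag clean names such as *Natronococcus*);
#' all other keywords match case-insensitively as substrings, after rank
#' prefixes (`d__`, `p__`, ...) are stripped and underscores normalized to
#' spaces.
#'
#' @param extra Additional keywords to append.
#' @return Character vector of keywords.
#' @export
mdm_keywords <- function(extra = character()) {
  unique(c("uncultured", "unknown", "unidentified", "NA", "unknown_family",
           "Incertae Sedis", "metagenome", "", extra))
}

# exact-match keywords (whole label); everything else is substring-matched
exact_match_keywords <- function() c("NA", "")

# normalize a label for matching: strip any rank prefix, underscores to
# spaces, trim, lower-case
normalize_label <- function(x) {
  x[is.na(x)] <- ""
  x <- stringr::str_replace(x, "^[dpcofgs]__", "")
  x <- stringr::str_replace_all(x, "_", " ")
  stringr::str_to_lower(stringr::str_trim(x))
}

label_is_mdm <- function(labels, keyword_set) {
  norm <- normalize_label(labels)
  exact <- normalize_label(intersect(keyword_set, exact_match_keywords()))
  subs <- normalize_label(setdiff(keyword_set, exact_match_keywords()))
  subs <- subs[nzchar(subs)]
  hit <- norm %in% exact
  for (k in subs) hit <- hit | stringr::str_detect(norm, stringr::fixed(k))
  hit
}

#' Relabel unknown taxa as microbial dark matter with downward propagation
#'
#' Scans each lineage from domain to species for the first rank whose label
#' matches an unknown-classification keyword; that rank and every rank below
#' it are relabeled `"MDM"` and flagged, so that e.g. an "unknown" at the
#' order level yields MDM at order, family, genus and species. Higher ranks
#' are untouched. The resulting flags are downward-monotone by construction.
#'
#' @param taxonomy Taxonomy tibble: `taxon_id` plus the seven rank columns
#'   from [tax_ranks()]. Missing (`NA`) labels count as unassigned.
#' @param keyword_set Keywords marking a label unknown; see [mdm_keywords()].
#' @return The taxonomy tibble with matched-and-below rank labels set to
#'   `"MDM"` and seven logical columns `mdm_domain` ... `mdm_species`
#'   appended.
#' @examples
#' tax <- tibble::tibble(taxon_id = "t1", domain = "Dom1", phylum = "Phy1",
#'   class = "Cla1", order = "unknown", family = "Fam1", genus = "Gen1",
#'   species = "Spe1")
#' relabel_mdm(tax)
#' @export
relabel_mdm <- function(taxonomy, keyword_set = mdm_keywords()) {
  if (length(keyword_set) == 0) abort("keyword_set must not be empty")
  ranks <- tax_ranks()
  if (!all(ranks %in% names(taxonomy))) {
    abort("taxonomy must contain all seven rank columns (see tax_ranks())")
  }
  lab <- as.matrix(taxonomy[ranks])
  hit <- vapply(seq_len(ncol(lab)), function(r) label_is_mdm(lab[, r], keyword_set),
                logical(nrow(lab)))
  hit <- matrix(hit, nrow = nrow(lab))
  # first flagged rank propagates to all lower ranks
  first <- apply(hit, 1, function(h) if (any(h)) which(h)[1] else 8L)
  flags <- outer(first, seq_len(7), `<=`)
  lab[flags] <- "MDM"
  out <- taxonomy
  out[ranks] <- as_tibble(lab)
  flags_tbl <- as_tibble(flags, .name_repair = "minimal")
  names(flags_tbl) <- paste0("mdm_", ranks)
  dplyr::bind_cols(out, flags_tbl)
}

#' Filtering rules for abundance tables
#'
#' Bundles the three taxon-level filters applied before network
#' construction: a prevalence threshold (taxon present, i.e. nonzero, in at
#' least `min_samples` samples), removal of excluded domains (by default
#' Eukaryota), and removal of taxa labeled "Chloroplast" at any of the
#' configured ranks.
#'
#' @param min_samples Prevalence threshold (>= 1). Typical values: 2 for
#'   amplicon surveys, and for deeper designs a majority-of-samples cut such
#'   as 15 of 24 (62.5%) or 34 of 55 (61.8%).
#' @param exclude_domains Domain labels removed outright.
#' @param chloroplast_ranks Ranks on which a "Chloroplast" label triggers
#'   removal.
#' @return A list of class `mdm_filter_config`.
#' @export
filter_config <- function(min_samples = 2L,
                          exclude_domains = "Eukaryota",
                          chloroplast_ranks = c("order", "family", "genus")) {
  if (min_samples < 1) abort("min_samples must be >= 1")
  bad <- setdiff(chloroplast_ranks, tax_ranks())
  if (length(bad)) abort(paste("unknown rank(s):", paste(bad, collapse = ", ")))
  structure(list(min_samples = as.integer(min_samples),
                 exclude_domains = exclude_domains,
                 chloroplast_ranks = chloroplast_ranks),
            class = "mdm_filter_config")
}

#' Prevalence threshold as a percentage of samples
#'
#' Reports `min_samples / n_samples` as a percentage rounded to one decimal,
#' the figure quoted when a prevalence cut is described as a fraction of the
#' study ("present in at least 15 of 24 samples, 62.5%").
#'
#' @param min_samples Prevalence threshold.
#' @param n_samples Total number of samples.
#' @return Percentage (single number).
#' @examples
#' prevalence_threshold_pct(15, 24)
#' prevalence_threshold_pct(34, 55)
#' @export
prevalence_threshold_pct <- function(min_samples, n_samples) {
  stopifnot(min_samples >= 1, n_samples >= min_samples)
  round(100 * min_samples / n_samples, 1)
}

#' Filter taxa by prevalence, domain and chloroplast labels
#'
#' Retains exactly the taxa with nonzero abundance in at least
#' `config$min_samples` samples, whose domain is not excluded, and which
#' carry no "Chloroplast" label on the configured ranks. The sample set is
#' unchanged. Idempotent.
#'
#' @param table Abundance tibble (`sample_id` + taxon columns).
#' @param taxonomy Taxonomy tibble covering every taxon in `table`.
#' @param config An [filter_config()] object.
#' @return The filtered abundance tibble, with a `filter_report` attribute
#'   (tibble of per-rule removal counts; see [filter_report()]).
#' @export
filter_taxa <- function(table, taxonomy, config = filter_config()) {
  stopifnot(inherits(config, "mdm_filter_config"))
  m <- abundance_matrix(table)
  taxa <- colnames(m)
  missing <- setdiff(taxa, taxonomy$taxon_id)
  if (length(missing)) {
    abort(paste("taxa missing from taxonomy:", paste(missing, collapse = ", ")))
  }
  tax <- taxonomy[match(taxa, taxonomy$taxon_id), ]

  prevalent <- colSums(m > 0) >= config$min_samples
  dom_ok <- !(normalize_label(tax$domain) %in% normalize_label(config$exclude_domains))
  chl <- rep(FALSE, length(taxa))
  for (r in config$chloroplast_ranks) {
    chl <- chl | stringr::str_detect(normalize_label(tax[[r]]), stringr::fixed("chloroplast"))
  }
  keep <- prevalent & dom_ok & !chl

  report <- tibble(
    n_taxa_in = length(taxa),
    n_taxa_out = sum(keep),
    n_below_prevalence = sum(!prevalent),
    n_excluded_domain = sum(!dom_ok),
    n_chloroplast = sum(chl),
    min_samples = config$min_samples,
    n_samples = nrow(m),
    prevalence_pct = prevalence_threshold_pct(config$min_samples, nrow(m))
  )
  out <- dplyr::select(as_tibble(table), "sample_id", all_of(taxa[keep]))
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the filter report attached by [filter_taxa()]
#'
#' @param table A filtered abundance tibble.
#' @return One-row tibble of per-rule removal counts and the prevalence
#'   threshold expressed as a percentage of samples.
#' @export
filter_report <- function(table) {
  rep <- attr(table, "filter_report")
  if (is.null(rep)) abort("table carries no filter report; run filter_taxa() first")
  rep
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' Sums the counts of taxa sharing an identical lineage prefix down to
#' `rank` into one node. Node identity is the full prefix (ranks joined by
#' `";"`), so an MDM label at `rank` does not merge across distinct known
#' parents: "MDM under Phy01" and "MDM under Phy02" remain separate nodes.
#' Total counts are conserved exactly.
#'
#' @param table Abundance tibble.
#' @param taxonomy Taxonomy tibble (typically after [relabel_mdm()]).
#' @param rank Aggregation rank, one of phylum ... genus.
#' @return List with `table` (aggregated abundance tibble, columns named by
#'   lineage prefix) and `lineage` (tibble mapping `node_id` to its rank
#'   labels and an `is_mdm` flag at `rank`).
#' @export
aggregate_to_rank <- function(table, taxonomy, rank) {
  ranks <- tax_ranks()
  if (!rank %in% ranks[2:6]) {
    abort("rank must be one of phylum, class, order, family, genus")
  }
  m <- abundance_matrix(table)
  taxa <- colnames(m)
  missing <- setdiff(taxa, taxonomy$taxon_id)
  if (length(missing)) {
    abort(paste("taxa missing from taxonomy:", paste(missing, collapse = ", ")))
  }
  depth <- match(rank, ranks)
  tax <- taxonomy[match(taxa, taxonomy$taxon_id), ]
  prefix_ranks <- ranks[seq_len(depth)]
  node_id <- apply(as.matrix(tax[prefix_ranks]), 1, paste, collapse = ";")

  groups <- unique(node_id)
  agg <- vapply(groups, function(g) rowSums(m[, node_id == g, drop = FALSE]),
                numeric(nrow(m)))
  agg <- matrix(agg, nrow = nrow(m), dimnames = list(rownames(m), groups))

  lineage <- as_tibble(tax[prefix_ranks])[match(groups, node_id), , drop = FALSE]
  lineage <- dplyr::bind_cols(tibble(node_id = groups), lineage)
  lineage$is_mdm <- lineage[[rank]] == "MDM"

  list(table = abundance_tibble(agg), lineage = lineage)
}

#' Compare known classifications across datasets at a rank
#'
#' For each distinct known label at `rank`, determines which datasets
#' contain it, and tallies exclusive (upset-style) intersection counts.
#' MDM labels are excluded from label identity: an unknown in one dataset is
#' never "shared" with an unknown in another.
#'
#' @param taxonomy_sets Named list (>= 2 entries) of taxonomy tibbles,
#'   typically after [relabel_mdm()].
#' @param rank Rank at which labels are compared.
#' @return Tibble with one row per non-empty dataset combination: `combo`
#'   (dataset names joined by `"&"`), `degree` (number of datasets in the
#'   combination) and `n_labels`. Rows with `degree == 1` are the
#'   per-dataset unique counts. The full label-by-dataset membership table
#'   is attached as attribute `"membership"`.
#' @examples
#' a <- tibble::tibble(taxon_id = c("x", "y"), phylum = c("P1", "P2"))
#' b <- tibble::tibble(taxon_id = c("u", "v"), phylum = c("P2", "P3"))
#' compare_datasets(list(A = a, B = b), "phylum")
#' @export
compare_datasets <- function(taxonomy_sets, rank) {
  if (length(taxonomy_sets) < 2 || is.null(names(taxonomy_sets))) {
    abort("taxonomy_sets must be a named list of at least 2 taxonomies")
  }
  if (!rank %in% tax_ranks()) abort(paste("unknown rank:", rank))
  labels_of <- function(tax) {
    lab <- tax[[rank]]
    flag_col <- paste0("mdm_", rank)
    if (flag_col %in% names(tax)) lab <- lab[!tax[[flag_col]]]
    lab <- unique(lab[!is.na(lab) & lab != "MDM" & nzchar(lab)])
    lab
  }
  sets <- purrr::map(taxonomy_sets, labels_of)
  all_labels <- sort(unique(unlist(sets)))
  membership <- tibble(label = all_labels)
  for (nm in names(sets)) membership[[nm]] <- all_labels %in% sets[[nm]]

  combo <- apply(as.matrix(membership[names(sets)]), 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  out <- membership |>
    mutate(combo = combo, degree = rowSums(dplyr::pick(all_of(names(sets))))) |>
    dplyr::count(.data$combo, .data$degree, name = "n_labels") |>
    arrange(desc(.data$degree), .data$combo)
  attr(out, "membership") <- membership
  out
}
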