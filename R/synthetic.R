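# Synthetic community generator: a known sparse conditional-dependence
# structure over taxa, logistic-normal-multinomial counts at variable
# sequencing depth, and SILVA-style taxonomy strings with controlled
# microbial-dark-matter (MDM) content. Used as ground truth for validating
# the inference pipeline end to end.

#' Generate a sparse association graph and its precision matrix
#'
#' Builds the ground-truth conditional-dependence structure for a synthetic
#' community: a sparse symmetric positive-definite precision matrix whose
#' off-diagonal support defines the true edge set. Three topologies are
#' offered: `band` (taxa linked to their `k` nearest neighbours in index
#' order, `k` set by `edge_density`), `hub` (non-hub taxa each attached to
#' one of a few hub taxa), and `random` (Erdos-Renyi edge placement).
#'
#' Off-diagonal precision entries are drawn uniformly in magnitude from
#' 0.25-0.45; `band` and `hub` use negative entries (positive partial
#' correlation, the typical co-occurrence signal), `random` uses random
#' signs. The diagonal is loaded uniformly until the condition number of the
#' precision matrix is at most `condition_target`; the loading applied is
#' recorded in the result.
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param graph_model One of `"band"`, `"hub"`, `"random"`.
#' @param edge_density Target fraction of the `n_taxa*(n_taxa-1)/2` possible
#'   edges; must yield at least one edge.
#' @param condition_target Target condition number of the precision matrix
#'   (> 1); smaller values give better-conditioned, easier-to-recover
#'   structure.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `mdm_truth`: `precision` (named matrix),
#'   `true_edges` (tibble `from`/`to`), `taxa`, `graph_model`,
#'   `diagonal_loading`.
#' @examples
#' g <- sim_association_graph(10, "band", edge_density = 0.1, seed = 1)
#' g$true_edges
#' @export
sim_association_graph <- function(n_taxa, graph_model = c("band", "hub", "random"),
                                  edge_density = 0.1, condition_target = 10,
                                  seed = NULL) {
  graph_model <- match.arg(graph_model)
  if (n_taxa < 3) abort("n_taxa must be at least 3")
  if (edge_density <= 0 || edge_density >= 1) abort("edge_density must be in (0, 1)")
  if (condition_target <= 1) abort("condition_target must exceed 1")
  n_pairs <- n_taxa * (n_taxa - 1) / 2
  taxa <- sprintf("t%03d", seq_len(n_taxa))

  with_seed_maybe(seed, {
    A <- matrix(0, n_taxa, n_taxa)
    if (graph_model == "band") {
      # bandwidth chosen so the band holds roughly density * n_pairs edges;
      # bandwidth 1 is the chain graph
      k <- max(1L, round(edge_density * n_pairs / (n_taxa - 1)))
      for (d in seq_len(min(k, n_taxa - 1))) {
        for (i in seq_len(n_taxa - d)) A[i, i + d] <- A[i + d, i] <- 1
      }
    } else if (graph_model == "hub") {
      n_hubs <- max(1L, round(edge_density * n_taxa))
      hubs <- seq_len(n_hubs)
      for (i in setdiff(seq_len(n_taxa), hubs)) {
        h <- if (n_hubs == 1L) 1L else sample(hubs, 1L)
        A[i, h] <- A[h, i] <- 1
      }
    } else {
      m <- round(edge_density * n_pairs)
      if (m < 1) abort("edge_density too low: no edges at this n_taxa")
      pairs <- which(upper.tri(A))
      chosen <- sample(pairs, m)
      A[chosen] <- 1
      A <- A + t(A)
    }
    if (sum(A) == 0) abort("edge_density too low: no edges at this n_taxa")

    magnitude <- matrix(runif(n_taxa^2, 0.25, 0.45), n_taxa)
    magnitude[lower.tri(magnitude)] <- t(magnitude)[lower.tri(magnitude)]
    sgn <- if (graph_model == "random") {
      s <- matrix(sample(c(-1, 1), n_taxa^2, replace = TRUE), n_taxa)
      s[lower.tri(s)] <- t(s)[lower.tri(s)]
      s
    } else {
      matrix(-1, n_taxa, n_taxa)
    }
    omega <- diag(n_taxa) + A * magnitude * sgn

    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    loading <- max(0, (ev[1] - condition_target * ev[n_taxa]) / (condition_target - 1))
    omega <- omega + loading * diag(n_taxa)
    ev2 <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (ev2[n_taxa] <= 0) {
      abort("internal failure: precision matrix not positive definite after diagonal loading")
    }
    dimnames(omega) <- list(taxa, taxa)

    idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
    true_edges <- canonical_edges(taxa[idx[, 1]], taxa[idx[, 2]], taxa)

    structure(
      list(precision = omega, true_edges = true_edges, taxa = taxa,
           graph_model = graph_model, diagonal_loading = loading),
      class = "mdm_truth"
    )
  })
}

#' @export
print.mdm_truth <- function(x, ...) {
  cat(sprintf("<mdm_truth> %s graph: %d taxa, %d true edges (diagonal loading %.3f)\n",
              x$graph_model, length(x$taxa), nrow(x$true_edges), x$diagonal_loading))
  invisible(x)
}

#' Sample abundance counts from a ground-truth association structure
#'
#' Draws samples from a logistic-normal-multinomial model: a latent Gaussian
#' vector with covariance equal to the inverse of the ground-truth precision
#' matrix is mapped through the softmax to a composition, and counts are
#' drawn from a multinomial at a per-sample sequencing depth sampled
#' uniformly from `depth_range`. This is the compositional count model whose
#' latent (CLR-scale) dependence structure the neighborhood-selection
#' estimator targets, so recovery tests against `true_edges` are meaningful.
#'
#' @param truth An `mdm_truth` object from [sim_association_graph()].
#' @param n_samples Number of samples (>= 2).
#' @param depth_range Length-2 integer vector: min/max sequencing depth.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Abundance tibble (`sample_id` + one count column per taxon); every
#'   row sums to its drawn depth.
#' @examples
#' g <- sim_association_graph(5, "band", edge_density = 0.2, seed = 1)
#' sim_counts(g, n_samples = 4, seed = 2)
#' @export
sim_counts <- function(truth, n_samples, depth_range = c(2000L, 10000L), seed = NULL) {
  stopifnot(inherits(truth, "mdm_truth"))
  if (n_samples < 2) abort("n_samples must be at least 2")
  if (length(depth_range) != 2 || any(depth_range < 1) || depth_range[1] > depth_range[2]) {
    abort("depth_range must be two positive integers, min <= max")
  }
  p <- length(truth$taxa)
  sigma <- tryCatch(solve(truth$precision),
                    error = function(e) abort("degenerate covariance: precision not invertible"))
  with_seed_maybe(seed, {
    z <- MASS::mvrnorm(n_samples, mu = rep(0, p), Sigma = sigma)
    z <- matrix(z, nrow = n_samples)
    comp <- exp(z - apply(z, 1, max))
    comp <- comp / rowSums(comp)
    depths <- sample(seq.int(depth_range[1], depth_range[2]), n_samples, replace = TRUE)
    counts <- t(vapply(seq_len(n_samples),
                       function(i) rmultinom(1, depths[i], comp[i, ])[, 1],
                       numeric(p)))
    colnames(counts) <- truth$taxa
    rownames(counts) <- sprintf("S%03d", seq_len(n_samples))
    abundance_tibble(counts)
  })
}

#' Generate SILVA-style taxonomy with controlled unknown-label content
#'
#' Builds a hierarchically consistent synthetic taxonomy (a fixed number of
#' clean parent clades per rank, so lineage prefixes nest properly), then
#' independently replaces each rank's label with an unknown-classification
#' keyword (e.g. "uncultured", "unknown", "NA", "Incertae Sedis") with the
#' per-rank probability requested in `mdm_fraction_by_rank`. The raw strings
#' emulate what a SILVA-trained classifier emits; downward propagation of
#' MDM status is applied later by [relabel_mdm()], not here.
#'
#' @param n_taxa Number of taxa.
#' @param mdm_fraction_by_rank Seven probabilities in \[0, 1\] (domain to
#'   species) that a rank label is replaced by an unknown keyword. The
#'   default profile rises steeply with depth, the pattern amplicon surveys
#'   of poorly characterised communities show.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Taxonomy tibble: `taxon_id` plus one character column per rank.
#' @examples
#' sim_taxonomy(4, mdm_fraction_by_rank = c(0, 0, 0, 1, 1, 1, 1), seed = 1)
#' @export
sim_taxonomy <- function(n_taxa,
                         mdm_fraction_by_rank = c(0.03, 0.06, 0.15, 0.30, 0.45, 0.70, 0.97),
                         seed = NULL) {
  if (length(mdm_fraction_by_rank) != 7 ||
      any(mdm_fraction_by_rank < 0 | mdm_fraction_by_rank > 1)) {
    abort("mdm_fraction_by_rank must be 7 fractions in [0, 1]")
  }
  ranks <- tax_ranks()
  taxa <- sprintf("t%03d", seq_len(n_taxa))
  # clean clade pool sizes per rank; children nest under parents so that
  # identical prefixes denote genuinely shared lineage
  pool <- pmin(c(2L, 4L, 6L, 10L, 14L, max(2L, ceiling(n_taxa / 2)), n_taxa),
               n_taxa)
  kw <- c("uncultured", "unknown", "NA", "unknown_family", "Incertae Sedis")

  with_seed_maybe(seed, {
    clade <- matrix(0L, n_taxa, 7)
    clade[, 1] <- sample.int(pool[1], n_taxa, replace = TRUE)
    for (r in 2:7) {
      # child index within parent keeps the hierarchy consistent
      sub <- sample.int(max(1L, ceiling(pool[r] / pool[r - 1])), n_taxa, replace = TRUE)
      clade[, r] <- (clade[, r - 1] - 1L) * max(1L, ceiling(pool[r] / pool[r - 1])) + sub
    }
    labels <- vapply(1:7, function(r) {
      sprintf("%s%02d", c("Dom", "Phy", "Cla", "Ord", "Fam", "Gen", "Spe")[r], clade[, r])
    }, character(n_taxa))
    labels <- matrix(labels, nrow = n_taxa)
    for (r in 1:7) {
      hit <- runif(n_taxa) < mdm_fraction_by_rank[r]
      if (any(hit)) labels[hit, r] <- sample(kw, sum(hit), replace = TRUE)
    }
    colnames(labels) <- ranks
    dplyr::bind_cols(tibble(taxon_id = taxa), as_tibble(labels))
  })
}

#' Generate a complete synthetic community
#'
#' Convenience wrapper tying [sim_association_graph()], [sim_counts()] and
#' [sim_taxonomy()] together under one seed (child seeds derived by
#' counter). The defaults are the package's reference study conditions for
#' validation experiments.
#'
#' @inheritParams sim_association_graph
#' @inheritParams sim_counts
#' @inheritParams sim_taxonomy
#' @param seed Integer seed driving all three generators.
#' @return List with elements `abundance` (tibble), `taxonomy` (tibble) and
#'   `truth` (`mdm_truth`).
#' @examples
#' comm <- sim_community(n_samples = 10, n_taxa = 6, seed = 1)
#' names(comm)
#' @export
sim_community <- function(n_samples, n_taxa, graph_model = "band",
                          edge_density = 0.1, condition_target = 10,
                          depth_range = c(2000L, 10000L),
                          mdm_fraction_by_rank = c(0.03, 0.06, 0.15, 0.30, 0.45, 0.70, 0.97),
                          seed = NULL) {
  truth <- sim_association_graph(n_taxa, graph_model, edge_density,
                                 condition_target, seed = child_seed(seed, 1))
  abundance <- sim_counts(truth, n_samples, depth_range, seed = child_seed(seed, 2))
  taxonomy <- sim_taxonomy(n_taxa, mdm_fraction_by_rank, seed = child_seed(seed, 3))
  list(abundance = abundance, taxonomy = taxonomy, truth = truth)
}
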