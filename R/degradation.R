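# Degradation analysis: compare the network without MDM nodes against the
# original and against a size-matched random-removal null (removing equally
# many KNOWN nodes), using rank-sum tests on per-node centrality
# distributions and fragmentation counts.

#' Induced subgraph after node removal
#'
#' @param network An `mdm_network`.
#' @param node_set Nodes to remove (must all exist).
#' @return The induced `mdm_network` on the remaining nodes.
#' @export
remove_nodes <- function(network, node_set) {
  stopifnot(inherits(network, "mdm_network"))
  unknown <- setdiff(node_set, network$nodes)
  if (length(unknown)) {
    abort(paste("unknown node id(s):", paste(unknown, collapse = ", ")))
  }
  keep_nodes <- setdiff(network$nodes, node_set)
  out <- network
  out$nodes <- keep_nodes
  out$edges <- filter(network$edges,
                      .data$from %in% keep_nodes & .data$to %in% keep_nodes)
  out
}

#' Size-matched random removal of known nodes
#'
#' For each replicate, removes a uniform random subset of the KNOWN
#' (non-MDM) nodes of the same size as the MDM node set. This null isolates
#' the effect of which nodes are removed from the effect of how many:
#' every replicate has exactly the node count of the MDM-removed network.
#'
#' @param network An `mdm_network`.
#' @param mdm_nodes Character vector of the network's MDM nodes.
#' @param n_reps Number of replicates (default 100).
#' @param seed Master seed; replicate seeds derived by counter.
#' @return List of `n_reps` induced `mdm_network`s.
#' @export
random_known_removal_null <- function(network, mdm_nodes, n_reps = 100L, seed = NULL) {
  stopifnot(inherits(network, "mdm_network"))
  mdm_nodes <- intersect(mdm_nodes, network$nodes)
  known <- setdiff(network$nodes, mdm_nodes)
  if (length(known) < length(mdm_nodes)) {
    abort("null undefined: fewer known nodes than MDM nodes to match")
  }
  lapply(seq_len(n_reps), function(r) {
    with_seed_maybe(child_seed(seed, r), {
      drop <- sample(known, length(mdm_nodes))
      remove_nodes(network, drop)
    })
  })
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Mann-Whitney rank-sum test with midrank ties. When both groups have at
#' most 8 observations the two-sided p-value is computed by exact
#' enumeration of all group assignments of the observed (tied) values;
#' larger groups use the normal approximation with tie-corrected variance
#' and continuity correction. If every value in both groups is identical the
#' p-value is 1 by convention.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return One-row tibble `statistic` (Mann-Whitney U for `sample_a`),
#'   `p_value`, `method`.
#' @examples
#' wilcoxon_compare(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_compare <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) abort("both samples must be non-empty")
  na <- length(sample_a)
  nb <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)  # midranks
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (stats::var(pooled) == 0) {
    return(tibble(statistic = u_obs, p_value = 1, method = "degenerate"))
  }
  if (na <= 8 && nb <= 8) {
    # exact: enumerate all C(na+nb, na) assignments of the observed ranks
    combos <- combn(na + nb, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact"
  } else {
    n <- na + nb
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      return(tibble(statistic = u_obs, p_value = 1, method = "degenerate"))
    }
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  tibble(statistic = u_obs, p_value = p, method = method)
}

#' Significance star bands
#'
#' Maps p-values to the conventional bands: `ns` (> 0.05), `*` (<= 0.05),
#' `**` (<= 0.01), `***` (<= 0.001), `****` (<= 0.0001).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of bands.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Degradation report: MDM removal vs size-matched random removal
#'
#' Builds the MDM-removed network and `n_reps` random-known-removal null
#' replicates, computes per-node degree, betweenness and closeness for the
#' original network, the MDM-removed network, and the pooled null
#' replicates, and tests each metric across the three network pairs with
#' [wilcoxon_compare()]. Fragmentation (component count, largest-component
#' fraction) is reported per network.
#'
#' @param network Original `mdm_network`.
#' @param mdm_nodes The network's MDM nodes.
#' @param n_reps Number of null replicates (default 100).
#' @param seed Master seed for the null.
#' @return An `mdm_degradation` object: `metrics` (long tibble: `network`,
#'   `metric`, `node`, `value`; null replicates pooled with their replicate
#'   index), `tests` (tibble: `metric`, `comparison`, `statistic`,
#'   `p_value`, `stars`), `fragmentation`, `n_removed`, `n_reps`.
#' @export
degradation_report <- function(network, mdm_nodes, n_reps = 100L, seed = NULL) {
  mdm_nodes <- intersect(mdm_nodes, network$nodes)
  no_mdm <- remove_nodes(network, mdm_nodes)
  nulls <- random_known_removal_null(network, mdm_nodes, n_reps, seed)

  metric_cols <- c("degree", "betweenness", "closeness")
  long_metrics <- function(net, label, rep = NA_integer_) {
    centrality_profile(net) |>
      select("node", all_of(metric_cols)) |>
      tidyr::pivot_longer(all_of(metric_cols), names_to = "metric",
                          values_to = "value") |>
      mutate(network = label, replicate = rep, .before = 1)
  }
  metrics <- bind_rows(
    long_metrics(network, "original"),
    long_metrics(no_mdm, "no_mdm"),
    purrr::imap(nulls, function(nt, r) long_metrics(nt, "null", as.integer(r))) |>
      bind_rows()
  )

  pairs <- list(c("original", "no_mdm"), c("original", "null"), c("no_mdm", "null"))
  tests <- purrr::map_dfr(metric_cols, function(met) {
    purrr::map_dfr(pairs, function(pr) {
      a <- metrics$value[metrics$network == pr[1] & metrics$metric == met]
      b <- metrics$value[metrics$network == pr[2] & metrics$metric == met]
      w <- wilcoxon_compare(a, b)
      tibble(metric = met, comparison = paste(pr, collapse = " vs "),
             statistic = w$statistic, p_value = w$p_value,
             stars = p_stars(w$p_value))
    })
  })

  frag_row <- function(net, label, rep = NA_integer_) {
    g <- glance(net)
    tibble(network = label, replicate = rep, n_nodes = g$n_nodes,
           n_edges = g$n_edges, n_components = g$n_components,
           largest_component_frac = g$largest_component_frac)
  }
  fragmentation <- bind_rows(
    frag_row(network, "original"),
    frag_row(no_mdm, "no_mdm"),
    purrr::imap(nulls, function(nt, r) frag_row(nt, "null", as.integer(r))) |>
      bind_rows()
  )

  structure(list(metrics = metrics, tests = tests, fragmentation = fragmentation,
                 n_removed = length(mdm_nodes), n_reps = as.integer(n_reps)),
            class = "mdm_degradation")
}

#' @export
print.mdm_degradation <- function(x, ...) {
  cat(sprintf("<mdm_degradation> %d MDM node(s) removed; %d null replicate(s)\n",
              x$n_removed, x$n_reps))
  print(x$tests)
  invisible(x)
}

#' @rdname degradation_report
#' @param x An `mdm_degradation`.
#' @param ... Unused.
#' @export
tidy.mdm_degradation <- function(x, ...) x$metrics

#' @rdname degradation_report
#' @export
glance.mdm_degradation <- function(x, ...) {
  x$tests |>
    mutate(key = paste(.data$metric, gsub(" ", "_", .data$comparison), sep = ".")) |>
    select("key", "p_value") |>
    tidyr::pivot_wider(names_from = "key", values_from = "p_value") |>
    mutate(n_removed = x$n_removed, n_reps = x$n_reps)
}

#' Box plots of centrality distributions across networks
#'
#' One panel per metric, comparing the original network, the MDM-removed
#' network and the pooled random-removal null.
#'
#' @param object An `mdm_degradation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdm_degradation <- function(object, ...) {
  d <- mutate(object$metrics,
              network = factor(.data$network, c("original", "no_mdm", "null")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$network, y = .data$value,
                                  fill = .data$network)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "per-node value") +
    ggplot2::theme_minimal()
}
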