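# Permutation bootstrap for edge significance: per-taxon abundance
# permutation breaks the sample-abundance association, the network is
# rebuilt B times, and original edges that recur too often under this null
# are judged spurious and removed.

#' Permute each taxon's abundances across samples
#'
#' Independently shuffles every taxon column, destroying the association
#' between sample and abundance while conserving each taxon's multiset of
#' values (per-sample totals are generally not conserved).
#'
#' @param table Abundance tibble or count matrix.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Abundance tibble of the same shape.
#' @export
permute_table <- function(table, seed = NULL) {
  m <- abundance_matrix(table)
  with_seed_maybe(seed, {
    perm <- apply(m, 2, function(col) col[sample.int(length(col))])
    perm <- matrix(perm, nrow = nrow(m), dimnames = dimnames(m))
    abundance_tibble(perm)
  })
}

#' Removal-count threshold of the bootstrap edge filter
#'
#' An original edge is removed when it appears in more than
#' `floor(alpha * B)` of the `B` permutation networks; at the reference
#' settings `alpha = 0.05`, `B = 5000` the threshold is 250 (251 appearances
#' remove an edge, 250 retain it).
#'
#' @param alpha Significance level in (0, 1).
#' @param B Number of bootstrap replicates.
#' @return Integer threshold count.
#' @examples
#' bootstrap_removal_threshold(0.05, 5000)
#' @export
bootstrap_removal_threshold <- function(alpha = 0.05, B = 5000L) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (B < 1) abort("B must be positive")
  as.integer(floor(alpha * B))
}

#' Count original edges in permutation-null networks
#'
#' Rebuilds the network from `B` per-taxon permuted copies of the table and
#' counts, for each edge of the original network, how many permutation
#' networks contain it. By default the penalty is fixed to the original
#' network's selected penalty (`reuse_penalty = TRUE`); with
#' `reuse_penalty = FALSE` stability selection is re-run inside every
#' replicate. Replicates whose fit fails are dropped and the effective
#' number of replicates reported.
#'
#' @param table Abundance tibble the original network was built from.
#' @param network The original `mdm_network`.
#' @param B Number of replicates (reference analyses use 5000; simulations
#'   here scale down).
#' @param alpha Significance level for the retain/remove verdict.
#' @param reuse_penalty Reuse the original selected penalty per replicate?
#' @param seed Master seed; replicate seeds are derived by counter.
#' @return Tibble `from`, `to`, `bootstrap_count`, `retained`, with
#'   attributes `B` (requested), `B_effective`, `alpha`, `threshold`.
#' @export
bootstrap_edge_support <- function(table, network, B = 5000L, alpha = 0.05,
                                   reuse_penalty = TRUE, seed = NULL) {
  stopifnot(inherits(network, "mdm_network"))
  m <- abundance_matrix(table)
  if (nrow(m) < 2) abort("need at least 2 samples")
  if (!identical(colnames(m), network$nodes)) {
    abort("table taxa must match network nodes (same order)")
  }
  thr <- bootstrap_removal_threshold(alpha, B)
  keys <- edge_key(network$edges)
  counts <- setNames(integer(length(keys)), keys)
  dropped <- 0L
  for (r in seq_len(B)) {
    rep_seed <- child_seed(seed, r)
    perm <- permute_table(m, seed = rep_seed)
    net_r <- tryCatch({
      if (reuse_penalty) {
        infer_network(perm, pseudocount = network$pseudocount %||% 1,
                      penalty = network$selected_penalty, rule = network$rule)
      } else {
        infer_network(perm, pseudocount = network$pseudocount %||% 1,
                      rule = network$rule, seed = child_seed(rep_seed, 1))
      }
    }, error = function(e) NULL)
    if (is.null(net_r)) {
      dropped <- dropped + 1L
      next
    }
    hit <- keys %in% edge_key(net_r$edges)
    counts[hit] <- counts[hit] + 1L
  }
  if (dropped > 0) {
    warn(sprintf("%d of %d bootstrap replicates failed and were dropped", dropped, B))
  }
  out <- network$edges |>
    select("from", "to") |>
    mutate(bootstrap_count = unname(counts),
           retained = .data$bootstrap_count <= thr)
  attr(out, "B") <- as.integer(B)
  attr(out, "B_effective") <- as.integer(B - dropped)
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- thr
  out
}

#' Remove edges that recur in the permutation null
#'
#' Drops exactly the original edges whose `bootstrap_count` exceeds
#' `floor(alpha * B)`; the node set is unchanged (isolated nodes allowed).
#'
#' @param network Original `mdm_network`.
#' @param supports Support tibble from [bootstrap_edge_support()]; must
#'   cover every original edge.
#' @param alpha,B Filter parameters; default to the values recorded on
#'   `supports`.
#' @return Filtered `mdm_network`.
#' @export
filter_edges <- function(network, supports, alpha = NULL, B = NULL) {
  stopifnot(inherits(network, "mdm_network"))
  alpha <- alpha %||% attr(supports, "alpha") %||% 0.05
  B <- B %||% attr(supports, "B") %||% 5000L
  thr <- bootstrap_removal_threshold(alpha, B)
  keys <- edge_key(network$edges)
  skeys <- edge_key(supports)
  missing <- setdiff(keys, skeys)
  if (length(missing)) {
    abort(paste("missing support records for", length(missing), "edge(s)"))
  }
  counts <- supports$bootstrap_count[match(keys, skeys)]
  keep <- counts <= thr
  out <- network
  out$edges <- network$edges[keep, , drop = FALSE]
  out
}
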