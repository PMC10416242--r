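# Kleinberg hub scoring and classical centralities of the filtered
# network, plus the top-k hub table annotated with (MDM-relabeled)
# taxonomy.

#' Kleinberg hub scores of an undirected network
#'
#' On an undirected graph the Kleinberg/HITS hub score reduces to the
#' principal-eigenvector centrality of the adjacency matrix. Scores are
#' computed by power iteration with a unit diagonal shift (`A + I` has the
#' same eigenvectors as `A` but a strictly dominant top eigenvalue, which
#' keeps the iteration convergent on bipartite components), started from the
#' all-ones vector for determinism and run to tolerance 1e-10. Scores are
#' scaled so the maximum is 1; nodes outside the dominant component(s),
#' including isolates, score 0. When several components tie for the top
#' eigenvalue, the ones start vector weights them equally.
#'
#' @param network An `mdm_network` (or square 0/1 adjacency matrix).
#' @param tol Convergence tolerance of the power iteration.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Tibble `node`, `hub_score`. An edgeless network yields all zeros
#'   with a warning.
#' @examples
#' star <- make_network(letters[1:4],
#'                      tibble::tibble(from = "a", to = c("b", "c", "d")))
#' hub_scores(star)  # center 1, leaves 1/sqrt(3)
#' @export
hub_scores <- function(network, tol = 1e-10, max_iter = 10000L) {
  a <- if (is.matrix(network)) network else network_adjacency(network)
  nodes <- rownames(a) %||% as.character(seq_len(nrow(a)))
  p <- nrow(a)
  if (sum(a) == 0) {
    warn("network has no edges; all hub scores are 0")
    return(tibble(node = nodes, hub_score = rep(0, p)))
  }
  v <- rep(1, p)
  shifted <- a + diag(p)
  for (it in seq_len(max_iter)) {
    w <- as.vector(shifted %*% v)
    w <- w / max(w)
    if (max(abs(w - v)) < tol) {
      v <- w
      break
    }
    v <- w
    if (it == max_iter) abort("hub score power iteration did not converge")
  }
  s <- abs(v)
  s[s < sqrt(tol)] <- 0  # nodes decayed out of the dominant eigenspace
  tibble(node = nodes, hub_score = s / max(s))
}

#' Degree, betweenness, closeness and hub score per node
#'
#' Conventions: degree is the incident edge count; betweenness is the
#' unnormalized Brandes sum of pair dependencies (undirected, each pair
#' counted once); closeness is computed within each connected component as
#' `(n_c - 1) / sum of distances`, with isolated nodes at 0.
#'
#' @param network An `mdm_network`.
#' @return Tibble `node`, `degree`, `betweenness`, `closeness`, `hub_score`.
#' @export
centrality_profile <- function(network) {
  g <- network_igraph(network)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  cls <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  cls[!is.finite(cls)] <- 0
  hs <- if (nrow(network$edges)) hub_scores(network)$hub_score
        else rep(0, length(network$nodes))
  tibble(node = network$nodes,
         degree = as.integer(deg[network$nodes]),
         betweenness = unname(btw[network$nodes]),
         closeness = unname(cls[network$nodes]),
         hub_score = hs)
}

#' Top-k hubs annotated with taxonomy
#'
#' Sorts nodes by hub score (descending; ties broken by stable
#' node-identifier order in `scores`) and attaches the lineage of each node.
#' MDM-relabeled lineages surface as `"MDM"` labels, reproducing the layout
#' of published top-hub tables.
#'
#' @param scores Tibble `node`, `hub_score` (from [hub_scores()]), or a
#'   [centrality_profile()] table.
#' @param taxonomy Taxonomy/lineage tibble keyed by `taxon_id` or `node_id`
#'   matching the node identifiers.
#' @param k Number of rows (default 20); if `k` exceeds the node count all
#'   nodes are returned.
#' @return Tibble of the `k` top hubs: `node`, `hub_score` and the available
#'   rank columns; attribute `"mdm_rank_counts"` holds the number of
#'   returned rows labeled MDM at each rank (see [mdm_rank_counts()]).
#' @export
top_hubs <- function(scores, taxonomy = NULL, k = 20L) {
  if (k < 1) abort("k must be >= 1")
  ord <- order(-scores$hub_score, seq_len(nrow(scores)))
  out <- scores[ord, , drop = FALSE] |> head(min(k, nrow(scores)))
  if (!is.null(taxonomy)) {
    key <- if ("node_id" %in% names(taxonomy)) "node_id" else "taxon_id"
    keep <- c(key, intersect(tax_ranks(), names(taxonomy)))
    out <- left_join(out, taxonomy[keep], by = c(node = key))
  }
  ranks_present <- intersect(tax_ranks(), names(out))
  counts <- vapply(ranks_present, function(r) sum(out[[r]] == "MDM", na.rm = TRUE),
                   integer(1))
  attr(out, "mdm_rank_counts") <- tibble(rank = ranks_present,
                                         n_mdm = unname(counts),
                                         n_rows = nrow(out))
  out
}

#' MDM counts per rank in a top-hub table
#'
#' @param top A table from [top_hubs()].
#' @return Tibble `rank`, `n_mdm`, `n_rows`.
#' @export
mdm_rank_counts <- function(top) {
  x <- attr(top, "mdm_rank_counts")
  if (is.null(x)) abort("not a top_hubs() table")
  x
}
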