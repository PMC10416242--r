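# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# Partial correlations from the Moore-Penrose inverse of the empirical
# covariance (CLR covariance is rank-deficient, so a pseudoinverse is used).
oracle_partial_cor <- function(x) {
  om <- MASS::ginv(stats::cov(x))
  pc <- -om / sqrt(outer(diag(om), diag(om)))
  diag(pc) <- 0
  pc
}

# Hub-score oracle: dense eigendecomposition of the adjacency matrix, with
# the degenerate top eigenspace resolved by projecting the all-ones start
# vector onto it (the package's documented convention), scaled to max 1.
oracle_hub_scores <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  top <- which(e$values > max(e$values) - 1e-8)
  v <- e$vectors[, top, drop = FALSE]
  proj <- as.vector(v %*% crossprod(v, rep(1, nrow(a))))
  s <- abs(proj)
  s[s < 1e-8] <- 0
  s / max(s)
}

# Betweenness oracle: Floyd-Warshall distances with shortest-path counting,
# then explicit pair-dependency sums. Unnormalized, each pair once.
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  d[a > 0] <- 1
  sigma[a > 0] <- 1
  diag(d) <- 0
  diag(sigma) <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        alt <- d[i, k] + d[k, j]
        if (alt < d[i, j]) {
          d[i, j] <- alt
          sigma[i, j] <- sigma[i, k] * sigma[k, j]
        } else if (is.finite(alt) && alt == d[i, j] && k != i && k != j) {
          sigma[i, j] <- sigma[i, j] + sigma[i, k] * sigma[k, j]
        }
      }
    }
  }
  bt <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq.int(s + 1, n)) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          bt[v] <- bt[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bt
}

# Exact two-sided rank-sum oracle: enumerate every assignment of the pooled
# values to group A and count pair wins directly (Mann-Whitney counting
# definition, not the rank-sum formula the implementation uses).
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    av <- pooled[idx]
    bv <- pooled[-idx]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(seq_len(na))
  mu <- na * length(b) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Edge-recovery F1 between a network and a ground-truth edge tibble
edge_f1 <- function(network, true_edges) {
  pred <- paste(network$edges$from, network$edges$to)
  truth <- paste(true_edges$from, true_edges$to)
  if (!length(pred) && !length(truth)) return(1)
  tp <- length(intersect(pred, truth))
  if (tp == 0) return(0)
  2 * tp / (length(pred) + length(truth))
}

# Random undirected graph as a 0/1 adjacency matrix with named nodes
random_adjacency <- function(n, p_edge = 0.3) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- stats::rbinom(length(up), 1, p_edge)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  a
}

adjacency_network <- function(a) {
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  make_network(rownames(a),
               tibble::tibble(from = rownames(a)[idx[, 1]],
                              to = colnames(a)[idx[, 2]]))
}

# Small clean seven-rank taxonomy for filter/aggregation tests
toy_taxonomy <- function(taxon_id, domain = "Bacteria", phylum = "PhyA",
                         class = "ClaA", order = "OrdA", family = "FamA",
                         genus = "GenA", species = "SpeA") {
  tibble::tibble(taxon_id = taxon_id, domain = domain, phylum = phylum,
                 class = class, order = order, family = family,
                 genus = genus, species = species)
}
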