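# Compositional co-occurrence network inference: centered log-ratio
# transform, Meinshausen-Buhlmann neighborhood selection (per-node lasso,
# solved by glmnet's coordinate descent), StARS stability selection of the
# penalty, and OR/AND symmetrization into an undirected network.

#' Centered log-ratio transform of an abundance table
#'
#' Maps counts to the unconstrained CLR scale:
#' `log(count + pseudocount) - rowMean(log(count + pseudocount))`. Every row
#' sums to zero. The pseudocount handles the zeros that dominate sparse OTU
#' tables; 1 is the conventional default.
#'
#' @param table Abundance tibble or samples-by-taxa count matrix.
#' @param pseudocount Positive value added to every count before the log.
#' @return Samples-by-taxa numeric matrix of CLR values, with attribute
#'   `pseudocount`.
#' @examples
#' clr_transform(matrix(c(1, 3), 1, 2, dimnames = list("s1", c("a", "b"))))
#' @export
clr_transform <- function(table, pseudocount = 1) {
  if (pseudocount <= 0) abort("pseudocount must be positive")
  m <- abundance_matrix(table)
  check_counts(m)
  l <- log(m + pseudocount)
  out <- l - rowMeans(l)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Null penalty: smallest penalty with all-empty neighborhoods
#'
#' The largest absolute inner product between any standardized predictor
#' column and any centered response column, divided by the sample size -- the
#' lasso's data-driven entry threshold. At or above this penalty every
#' neighborhood regression selects nothing.
#'
#' @param clr CLR matrix from [clr_transform()].
#' @return Single positive number.
#' @export
mb_null_penalty <- function(clr) {
  n <- nrow(clr)
  p <- ncol(clr)
  cs <- scale(clr, center = TRUE, scale = FALSE)
  sds <- sqrt(colMeans(cs^2))
  sds[sds == 0] <- 1
  std <- sweep(cs, 2, sds, "/")
  g <- abs(crossprod(std, cs)) / n  # [k, j] = |<x_k std, y_j centered>|/n
  diag(g) <- 0
  max(g)
}

#' Default penalty path for neighborhood selection
#'
#' `length`-point log-spaced grid from the data-driven null penalty (see
#' [mb_null_penalty()]) down to `min_ratio` times it, in decreasing order.
#'
#' @param clr CLR matrix.
#' @param length Number of penalties.
#' @param min_ratio Smallest penalty as a fraction of the null penalty.
#' @return Decreasing numeric vector.
#' @export
default_penalty_path <- function(clr, length = 20L, min_ratio = 0.01) {
  lam <- mb_null_penalty(clr)
  exp(seq(log(lam), log(lam * min_ratio), length.out = length))
}

# Fit all p neighborhood lassos along a penalty path.
# Returns, per penalty, a p x p matrix of signed coefficients (row j holds
# the regression of column j on the others).
mb_fit_path <- function(clr, path) {
  p <- ncol(clr)
  if (nrow(clr) < 3) abort("need at least 3 samples for neighborhood selection")
  if (any(path <= 0)) abort("penalties must be positive")
  nodes <- colnames(clr)
  coefs <- lapply(seq_along(path), function(l) {
    m <- matrix(0, p, p, dimnames = list(nodes, nodes))
    m
  })
  for (j in seq_len(p)) {
    fit <- tryCatch(
      glmnet::glmnet(clr[, -j, drop = FALSE], clr[, j], family = "gaussian",
                     lambda = path, standardize = TRUE, thresh = 1e-6),
      error = function(e) {
        abort(sprintf("neighborhood regression failed for node %s: %s",
                      nodes[j], conditionMessage(e)))
      }
    )
    b <- as.matrix(stats::coef(fit, s = path, exact = FALSE))[-1, , drop = FALSE]
    idx <- setdiff(seq_len(p), j)
    for (l in seq_along(path)) coefs[[l]][j, idx] <- b[, l]
  }
  coefs
}

#' Per-node signed neighborhoods at one penalty
#'
#' Runs the Meinshausen-Buhlmann step: for each node `j`, the L1-penalized
#' linear regression of CLR column `j` on all other columns (predictors
#' standardized; coordinate descent to tolerance 1e-6). Neighbors are the
#' predictors with nonzero coefficients.
#'
#' @param clr CLR matrix.
#' @param penalty Single positive penalty.
#' @return Tibble `node`, `neighbor`, `coefficient` (nonzero entries only),
#'   with the full signed coefficient matrix as attribute `"coef_matrix"`.
#' @export
mb_neighborhoods <- function(clr, penalty) {
  stopifnot(length(penalty) == 1)
  cm <- mb_fit_path(clr, penalty)[[1]]
  idx <- which(cm != 0, arr.ind = TRUE)
  out <- tibble(node = rownames(cm)[idx[, 1]],
                neighbor = colnames(cm)[idx[, 2]],
                coefficient = cm[idx]) |>
    arrange(match(.data$node, rownames(cm)), match(.data$neighbor, colnames(cm)))
  attr(out, "coef_matrix") <- cm
  out
}

# neighborhood coefficient matrix -> symmetric logical adjacency
symmetrize_matrix <- function(cm, rule) {
  sel <- cm != 0
  if (rule == "OR") sel | t(sel) else sel & t(sel)
}

#' Symmetrize directed neighborhoods into an undirected edge set
#'
#' `OR`: edge (i, j) when either node selects the other; `AND`: both
#' required. `OR` is the default throughout the package -- it preserves more
#' structure for the downstream degradation analysis.
#'
#' @param neighborhoods Output of [mb_neighborhoods()] (or a square signed
#'   coefficient matrix).
#' @param rule `"OR"` or `"AND"`.
#' @return Edge tibble `from`, `to`, `sign` (sign of the summed pairwise
#'   coefficients).
#' @export
symmetrize <- function(neighborhoods, rule = c("OR", "AND")) {
  rule <- match.arg(rule)
  cm <- if (is.matrix(neighborhoods)) neighborhoods else attr(neighborhoods, "coef_matrix")
  if (is.null(cm)) abort("neighborhoods must carry a coef_matrix attribute")
  adj <- symmetrize_matrix(cm, rule)
  diag(adj) <- FALSE
  nodes <- rownames(cm)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  canonical_edges(nodes[idx[, 1]], nodes[idx[, 2]], nodes,
                  sign = sign(cm[idx] + t(cm)[idx]))
}

#' StARS: stability selection of the lasso penalty
#'
#' For each penalty on the path, networks are rebuilt on `n_subsamples`
#' random subsamples (size `subsample_ratio * n`, drawn without
#' replacement) and the average edge-selection instability
#' `mean over pairs of 2 * p_hat * (1 - p_hat)` is computed, where `p_hat`
#' is a pair's selection frequency across subsamples. Instability is
#' monotonized by a running supremum from the sparse end of the path, and
#' the smallest penalty (densest graph) whose monotonized instability stays
#' at or below `threshold` is selected; if no penalty qualifies the sparsest
#' one is returned.
#'
#' @param clr CLR matrix.
#' @param path Decreasing positive penalty path; default
#'   [default_penalty_path()].
#' @param n_subsamples Number of subsamples (>= 2).
#' @param subsample_ratio Subsample size as a fraction of `n`; default
#'   `min(0.8, 10 * sqrt(n) / n)`.
#' @param threshold Instability threshold (default 0.05).
#' @param rule Symmetrization rule used when counting edges.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List: `selected_penalty`, `selected_index`, `instability`
#'   (tibble `penalty`, `instability`, `monotone_instability`).
#' @export
stars_select <- function(clr, path = NULL, n_subsamples = 20L,
                         subsample_ratio = NULL, threshold = 0.05,
                         rule = c("OR", "AND"), seed = NULL) {
  rule <- match.arg(rule)
  if (is.null(path)) path <- default_penalty_path(clr)
  if (length(path) == 0) abort("penalty path is empty")
  if (any(diff(path) >= 0)) abort("penalty path must be strictly decreasing")
  if (n_subsamples < 2) abort("n_subsamples must be >= 2")
  n <- nrow(clr)
  p <- ncol(clr)
  if (is.null(subsample_ratio)) subsample_ratio <- min(0.8, 10 * sqrt(n) / n)
  b <- max(3L, floor(subsample_ratio * n))

  counts <- lapply(seq_along(path), function(l) matrix(0, p, p))
  with_seed_maybe(seed, {
    for (s in seq_len(n_subsamples)) {
      idx <- sample.int(n, b)
      cms <- mb_fit_path(clr[idx, , drop = FALSE], path)
      for (l in seq_along(path)) {
        counts[[l]] <- counts[[l]] + symmetrize_matrix(cms[[l]], rule)
      }
    }
  })
  n_pairs <- p * (p - 1) / 2
  instab <- vapply(seq_along(path), function(l) {
    ph <- counts[[l]][upper.tri(counts[[l]])] / n_subsamples
    sum(2 * ph * (1 - ph)) / n_pairs
  }, numeric(1))
  mono <- cummax(instab)
  ok <- which(mono <= threshold)
  sel <- if (length(ok)) max(ok) else 1L
  list(selected_penalty = path[sel],
       selected_index = sel,
       instability = tibble(penalty = path, instability = instab,
                            monotone_instability = mono))
}

#' Infer a compositional co-occurrence network
#'
#' End-to-end Meinshausen-Buhlmann inference: CLR transform (when given
#' counts), StARS penalty selection, neighborhood fits at the selected
#' penalty, and symmetrization into an undirected, unweighted network.
#'
#' @param table Abundance tibble or count matrix (or an already-transformed
#'   CLR matrix with `clr = TRUE`).
#' @param pseudocount CLR pseudocount.
#' @param clr Set `TRUE` if `table` is already on the CLR scale.
#' @param path Penalty path; default [default_penalty_path()].
#' @param penalty Optional single penalty; skips StARS when given.
#' @param rule Symmetrization rule, `"OR"` (default) or `"AND"`.
#' @inheritParams stars_select
#' @return An `mdm_network` object: fields `nodes`, `edges` (tibble
#'   `from`/`to`/`sign`), `selected_penalty`, `penalty_path`, `instability`,
#'   `rule`, `pseudocount`, `seed`.
#' @examples
#' comm <- sim_community(n_samples = 40, n_taxa = 8, seed = 1)
#' net <- infer_network(comm$abundance, seed = 2)
#' net
#' @export
infer_network <- function(table, pseudocount = 1, clr = FALSE, path = NULL,
                          penalty = NULL, rule = c("OR", "AND"),
                          n_subsamples = 20L, subsample_ratio = NULL,
                          threshold = 0.05, seed = NULL) {
  rule <- match.arg(rule)
  cmat <- if (clr) table else clr_transform(table, pseudocount)
  if (is.null(colnames(cmat))) abort("input must carry taxon names")
  if (is.null(path)) path <- default_penalty_path(cmat)

  if (is.null(penalty)) {
    st <- stars_select(cmat, path, n_subsamples, subsample_ratio, threshold,
                       rule, seed = seed)
    penalty <- st$selected_penalty
    instab <- st$instability
  } else {
    if (!any(abs(path - penalty) / penalty < 1e-12)) {
      path <- sort(unique(c(path, penalty)), decreasing = TRUE)
    }
    instab <- NULL
  }
  cm <- mb_fit_path(cmat, penalty)[[1]]
  edges <- symmetrize(cm, rule)
  new_mdm_network(nodes = colnames(cmat), edges = edges,
                  selected_penalty = penalty, penalty_path = path,
                  instability = instab, rule = rule,
                  pseudocount = if (clr) attr(table, "pseudocount") %||% NA_real_ else pseudocount,
                  seed = seed)
}

new_mdm_network <- function(nodes, edges, selected_penalty = NA_real_,
                            penalty_path = numeric(), instability = NULL,
                            rule = "OR", pseudocount = NA_real_, seed = NULL) {
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes),
            !any(edges$from == edges$to))
  structure(list(nodes = nodes, edges = edges,
                 selected_penalty = selected_penalty,
                 penalty_path = penalty_path, instability = instability,
                 rule = rule, pseudocount = pseudocount, seed = seed),
            class = "mdm_network")
}

#' Construct a network from an explicit edge list
#'
#' Mainly for tests and examples; pipeline networks come from
#' [infer_network()].
#'
#' @param nodes Character vector of node identifiers.
#' @param edges Tibble/data frame with columns `from` and `to` (subset of
#'   `nodes`), or NULL for an edgeless network.
#' @return An `mdm_network`.
#' @export
make_network <- function(nodes, edges = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character(), sign = numeric())
  } else {
    edges <- canonical_edges(edges$from, edges$to, nodes,
                             sign = if ("sign" %in% names(edges)) edges$sign else rep(1, nrow(edges)))
  }
  new_mdm_network(nodes = nodes, edges = edges)
}

#' @export
print.mdm_network <- function(x, ...) {
  cat(sprintf("<mdm_network> %d nodes, %d edges (rule %s%s)\n",
              length(x$nodes), nrow(x$edges), x$rule,
              if (is.finite(x$selected_penalty))
                sprintf(", penalty %.4g", x$selected_penalty) else ""))
  invisible(x)
}

#' @rdname infer_network
#' @param x An `mdm_network`.
#' @param ... Unused.
#' @export
tidy.mdm_network <- function(x, ...) x$edges

#' @rdname infer_network
#' @export
glance.mdm_network <- function(x, ...) {
  g <- network_igraph(x)
  comp <- igraph::components(g)
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         selected_penalty = x$selected_penalty,
         n_components = comp$no,
         largest_component_frac = max(comp$csize) / length(x$nodes),
         rule = x$rule)
}

# mdm_network -> igraph (keeps isolated nodes)
network_igraph <- function(net) {
  stopifnot(inherits(net, "mdm_network"))
  igraph::graph_from_data_frame(net$edges[c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

# symmetric 0/1 adjacency matrix
network_adjacency <- function(net) {
  p <- length(net$nodes)
  a <- matrix(0, p, p, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    a[cbind(i, j)] <- 1
    a[cbind(j, i)] <- 1
  }
  a
}
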