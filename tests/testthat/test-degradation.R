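path5 <- function() {
  ids <- paste0("n", 1:5)
  make_network(ids, tibble::tibble(from = ids[1:4], to = ids[2:5]))
}

test_that("node removal induces the correct subgraph", {
  # cutting the center of a 5-path splits one component into two
  g0 <- igraph::components(microdark:::network_igraph(path5()))
  expect_equal(g0$no, 1)
  cut <- remove_nodes(path5(), "n3")
  expect_equal(igraph::components(microdark:::network_igraph(cut))$no, 2)
  # empty removal is the identity
  expect_equal(remove_nodes(path5(), character()), path5())
  # removing a star leaf keeps one component, drops one edge
  star <- make_network(letters[1:4],
                       tibble::tibble(from = "a", to = c("b", "c", "d")))
  leafless <- remove_nodes(star, "d")
  expect_equal(nrow(leafless$edges), 2)
  expect_equal(igraph::components(microdark:::network_igraph(leafless))$no, 1)
  expect_error(remove_nodes(star, "nope"), "unknown node")
})

test_that("removing nodes never merges surviving components", {
  withr::with_seed(31, {
    for (i in 1:20) {
      a <- random_adjacency(10, 0.2)
      net <- adjacency_network(a)
      drop <- sample(net$nodes, 3)
      survivors <- setdiff(net$nodes, drop)
      memb <- igraph::components(microdark:::network_igraph(net))$membership
      sub <- remove_nodes(net, drop)
      memb_sub <- igraph::components(microdark:::network_igraph(sub))$membership
      # two survivors in one induced component were already together before
      for (ci in unique(memb_sub)) {
        nodes_ci <- names(memb_sub)[memb_sub == ci]
        expect_equal(length(unique(memb[nodes_ci])), 1)
      }
    }
  })
})

test_that("size-matched null replicates remove exactly as many known nodes", {
  net <- path5()
  reps <- random_known_removal_null(net, mdm_nodes = c("n1", "n2"),
                                    n_reps = 10, seed = 1)
  expect_length(reps, 10)
  for (r in reps) {
    expect_equal(length(r$nodes), 3)
    # MDM nodes are never removed by the null
    expect_true(all(c("n1", "n2") %in% r$nodes))
  }
  # empty MDM set: every replicate is the original network
  reps0 <- random_known_removal_null(net, character(), n_reps = 3, seed = 2)
  expect_true(all(vapply(reps0, function(r) identical(r, net), logical(1))))
  expect_error(random_known_removal_null(net, paste0("n", 1:4), 5, seed = 3),
               "null undefined")
})

test_that("rank-sum test matches exact enumeration for all group sizes <= 6", {
  withr::with_seed(17, {
    for (i in 1:40) {
      na <- sample(2:6, 1)
      nb <- sample(2:6, 1)
      # integer draws force ties regularly
      a <- sample(0:4, na, replace = TRUE)
      b <- sample(0:5, nb, replace = TRUE)
      if (stats::var(c(a, b)) == 0) next
      got <- wilcoxon_compare(a, b)
      expect_equal(got$p_value, oracle_wilcoxon_p(a, b), tolerance = 1e-12)
      # symmetry in the two samples
      expect_equal(wilcoxon_compare(b, a)$p_value, got$p_value)
    }
  })
})

test_that("rank-sum agrees with stats::wilcox.test where both are exact or approximate", {
  expect_equal(wilcoxon_compare(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  withr::with_seed(23, {
    # tie-free small samples: both sides exact
    for (i in 1:10) {
      a <- sample(1:100, 5); b <- sample(101:200, 6)
      a <- a + runif(5); b <- b - runif(6)
      expect_equal(wilcoxon_compare(a, b)$p_value,
                   stats::wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-10)
    }
    # large samples: both sides normal approximation with continuity correction
    a <- rnorm(30); b <- rnorm(25, mean = 0.5)
    expect_equal(wilcoxon_compare(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-6)
  })
  expect_equal(wilcoxon_compare(rep(2, 4), rep(2, 5))$p_value, 1)
  expect_equal(wilcoxon_compare(c(1, 1, 2), c(1, 2, 1))$p_value, 1)
  expect_error(wilcoxon_compare(numeric(), 1:3), "non-empty")
})

test_that("p-values map to the conventional star bands", {
  expect_equal(p_stars(c(0.2, 0.051, 0.03, 0.009, 0.0005, 0.00005)),
               c("ns", "ns", "*", "**", "***", "****"))
})

test_that("a report with no MDM nodes is all non-significant", {
  g <- sim_association_graph(8, "band", 0.15, seed = 60)
  ab <- sim_counts(g, 80, seed = 61)
  net <- infer_network(ab, seed = 62)
  rep <- degradation_report(net, character(), n_reps = 5, seed = 63)
  expect_equal(rep$n_removed, 0)
  expect_true(all(rep$tests$stars == "ns"))
  expect_true(all(rep$tests$p_value == 1 |
                    rep$tests$comparison != "original vs no_mdm"))
  frag <- rep$fragmentation
  expect_equal(frag$n_nodes[frag$network == "no_mdm"],
               frag$n_nodes[frag$network == "original"])
})

test_that("planted MDM hubs degrade centrality below the size-matched null", {
  # a bridged double star whose two centers are the MDM set: removing them
  # isolates every peripheral node, while removing two random peripheral
  # (known) nodes leaves a connected star pair
  periph <- sprintf("p%02d", 1:10)
  hubs <- c("mdm1", "mdm2")
  edges <- dplyr::bind_rows(
    tibble::tibble(from = "mdm1", to = periph[1:5]),
    tibble::tibble(from = "mdm2", to = periph[6:10]),
    tibble::tibble(from = "mdm1", to = "mdm2")
  )
  net <- make_network(c(hubs, periph), edges)
  rep <- degradation_report(net, hubs, n_reps = 30, seed = 77)
  expect_equal(rep$n_removed, 2)

  frag <- rep$fragmentation
  n_orig <- frag$n_components[frag$network == "original"]
  n_nomdm <- frag$n_components[frag$network == "no_mdm"]
  expect_gt(n_nomdm, n_orig)

  med <- function(network, metric) {
    stats::median(rep$metrics$value[rep$metrics$network == network &
                                      rep$metrics$metric == metric])
  }
  expect_lt(med("no_mdm", "degree"), med("null", "degree"))
  expect_lt(med("no_mdm", "closeness"), med("null", "closeness"))
})

test_that("degradation tidiers and plot scaffolding work", {
  net <- path5()
  rep <- degradation_report(net, "n1", n_reps = 4, seed = 5)
  td <- tidy(rep)
  expect_true(all(c("network", "metric", "node", "value") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$n_removed, 1)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
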