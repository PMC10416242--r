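triangle <- function() {
  make_network(c("a", "b", "c"),
               tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c")))
}

test_that("hub scores reproduce closed-form symmetric cases", {
  expect_equal(hub_scores(triangle())$hub_score, rep(1, 3))

  star <- make_network(letters[1:4],
                       tibble::tibble(from = "a", to = c("b", "c", "d")))
  hs <- hub_scores(star)
  expect_equal(hs$hub_score[hs$node == "a"], 1)
  expect_equal(hs$hub_score[hs$node != "a"], rep(1 / sqrt(3), 3),
               tolerance = 1e-8)
})

test_that("isolated nodes score zero and edgeless networks warn", {
  tri_iso <- make_network(c("a", "b", "c", "x", "y"),
                          tibble::tibble(from = c("a", "a", "b"),
                                         to = c("b", "c", "c")))
  hs <- hub_scores(tri_iso)
  expect_equal(hs$hub_score[hs$node %in% c("x", "y")], c(0, 0))
  expect_equal(hs$hub_score[hs$node %in% c("a", "b", "c")], rep(1, 3))

  expect_warning(hs0 <- hub_scores(make_network(c("a", "b"))), "no edges")
  expect_equal(hs0$hub_score, c(0, 0))
})

test_that("hub scores match the dense eigendecomposition oracle on random graphs", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(3:15, 1)
      a <- random_adjacency(n, p_edge = runif(1, 0.15, 0.6))
      if (sum(a) == 0) next
      got <- hub_scores(a)$hub_score
      expect_equal(got, oracle_hub_scores(a), tolerance = 1e-6)
    }
  })
})

test_that("hub scores agree with igraph eigenvector centrality on connected non-bipartite graphs", {
  withr::with_seed(8, {
    checked <- 0
    while (checked < 25) {
      a <- random_adjacency(sample(4:12, 1), p_edge = 0.5)
      g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
      if (!igraph::is_connected(g) || igraph::is_bipartite(g)) next
      ec <- igraph::eigen_centrality(g)$vector
      expect_equal(hub_scores(a)$hub_score, unname(ec[rownames(a)]),
                   tolerance = 1e-6)
      checked <- checked + 1
    }
  })
})

test_that("relabeling nodes permutes hub scores consistently; isolates change nothing", {
  a <- random_adjacency(8, 0.4)
  withr::with_seed(3, while (sum(a) == 0) a <- random_adjacency(8, 0.4))
  net <- adjacency_network(a)
  base <- hub_scores(net)
  perm <- sample(8)
  ap <- a[perm, perm]
  got <- hub_scores(ap)
  expect_equal(got$hub_score[match(base$node, got$node)], base$hub_score,
               tolerance = 1e-9)
  # adding an isolated node leaves existing scores untouched
  net_iso <- make_network(c(net$nodes, "zzz"), net$edges)
  with_iso <- hub_scores(net_iso)
  expect_equal(with_iso$hub_score[match(base$node, with_iso$node)],
               base$hub_score, tolerance = 1e-9)
  expect_equal(with_iso$hub_score[with_iso$node == "zzz"], 0)
})

test_that("centrality conventions: path center mediates, complete graph is flat", {
  path3 <- make_network(c("x", "y", "z"),
                        tibble::tibble(from = c("x", "y"), to = c("y", "z")))
  prof <- centrality_profile(path3)
  expect_equal(prof$betweenness[prof$node == "y"], 1)
  expect_equal(prof$betweenness[prof$node != "y"], c(0, 0))
  expect_equal(prof$degree[prof$node == "y"], 2L)

  k4 <- make_network(letters[1:4],
                     tibble::tibble(from = c("a", "a", "a", "b", "b", "c"),
                                    to = c("b", "c", "d", "c", "d", "d")))
  p4 <- centrality_profile(k4)
  expect_equal(p4$betweenness, rep(0, 4))
  expect_equal(p4$closeness, rep(1, 4))
  # isolated node: closeness and betweenness 0
  iso <- centrality_profile(make_network(c("a", "b", "c"),
                                         tibble::tibble(from = "a", to = "b")))
  expect_equal(iso$closeness[iso$node == "c"], 0)
  expect_equal(iso$betweenness[iso$node == "c"], 0)
})

test_that("betweenness matches exhaustive shortest-path enumeration on 12-node graphs", {
  withr::with_seed(21, {
    for (i in 1:10) {
      a <- random_adjacency(12, p_edge = runif(1, 0.15, 0.4))
      prof <- centrality_profile(adjacency_network(a))
      expect_equal(prof$betweenness, oracle_betweenness(a), tolerance = 1e-9)
    }
  })
})

test_that("top_hubs sorts by score with stable identifier tie-break and annotates lineage", {
  scores <- tibble::tibble(node = c("b", "a", "c"), hub_score = c(1.0, 0.5, 0.5))
  tax <- relabel_mdm(toy_taxonomy(c("a", "b", "c"),
                                  domain = c("NA", "Bacteria", "Bacteria")))
  top2 <- top_hubs(scores, tax, k = 2)
  expect_equal(top2$node, c("b", "a"))
  expect_equal(top_hubs(scores, tax, k = 1)$node, "b")
  # k beyond node count returns everything
  expect_equal(nrow(top_hubs(scores, tax, k = 10)), 3)

  allk <- top_hubs(scores, tax, k = 3)
  expect_equal(allk$domain, c("Bacteria", "MDM", "Bacteria"))
  counts <- mdm_rank_counts(allk)
  expect_equal(counts$n_mdm[counts$rank == "domain"], 1L)
  expect_equal(counts$n_rows[1], 3L)
})

test_that("MDM share of top hubs is counted per rank on a planted fixture", {
  # 20 nodes, 8 of which are domain-MDM: the count reports 8 of 20
  ids <- sprintf("h%02d", 1:20)
  scores <- tibble::tibble(node = ids, hub_score = seq(1, 0.05, length.out = 20))
  dom <- c(rep("NA", 8), rep("Bacteria", 12))
  tax <- relabel_mdm(toy_taxonomy(ids, domain = dom))
  top <- top_hubs(scores, tax, k = 20)
  counts <- mdm_rank_counts(top)
  expect_equal(counts$n_mdm[counts$rank == "domain"], 8L)
  expect_equal(counts$n_mdm[counts$rank == "domain"] / counts$n_rows[1], 0.4)
})
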