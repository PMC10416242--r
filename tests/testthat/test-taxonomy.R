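test_that("an unknown at order propagates MDM to order, family, genus and species", {
  tax <- toy_taxonomy("t1", order = "unknown")
  rel <- relabel_mdm(tax)
  expect_equal(unlist(rel[1, tax_ranks()], use.names = FALSE),
               c("Bacteria", "PhyA", "ClaA", "MDM", "MDM", "MDM", "MDM"))
  expect_equal(unlist(rel[1, paste0("mdm_", tax_ranks())], use.names = FALSE),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("clean lineages are untouched and a domain-level NA flags all ranks", {
  clean <- relabel_mdm(toy_taxonomy("t1"))
  expect_false(any(unlist(clean[1, paste0("mdm_", tax_ranks())])))
  expect_equal(unlist(clean[1, tax_ranks()], use.names = FALSE),
               unlist(toy_taxonomy("t1")[1, tax_ranks()], use.names = FALSE))

  top <- relabel_mdm(toy_taxonomy("t1", domain = "NA"))
  expect_true(all(unlist(top[1, paste0("mdm_", tax_ranks())])))
})

test_that("keyword matching is substring-based except for NA and the empty label", {
  # embedded keyword with prefix and underscores
  emb <- relabel_mdm(toy_taxonomy("t1", family = "f__Rhizobiales_Incertae_Sedis"))
  expect_true(emb$mdm_family)
  # clean names containing the letters "na" must not be flagged
  na_like <- relabel_mdm(toy_taxonomy("t1", genus = "Natronococcus",
                                      family = "Nodosilineaceae"))
  expect_false(any(unlist(na_like[1, paste0("mdm_", tax_ranks())])))
  # missing labels count as unassigned
  gap <- relabel_mdm(toy_taxonomy("t1", genus = ""))
  expect_true(gap$mdm_genus && gap$mdm_species)
  expect_error(relabel_mdm(toy_taxonomy("t1"), keyword_set = character()),
               "keyword_set")
})

test_that("MDM flags are downward-monotone for random keyword placements", {
  withr::with_seed(42, {
    for (i in 1:50) {
      labels <- matrix("Clean", 1, 7)
      hits <- which(runif(7) < 0.4)
      labels[hits] <- sample(mdm_keywords()[1:6], length(hits), replace = TRUE)
      tax <- toy_taxonomy("t1")
      tax[tax_ranks()] <- as.list(labels)
      flags <- unlist(relabel_mdm(tax)[1, paste0("mdm_", tax_ranks())])
      expect_true(all(diff(flags) >= 0))  # once TRUE, stays TRUE downward
    }
  })
})

make_toy_table <- function() {
  # presence pattern per taxon across 3 samples: 1, 2, 3, 0 samples
  abundance_tibble(matrix(
    c(5, 0, 0,
      2, 3, 0,
      1, 1, 1,
      0, 0, 0),
    nrow = 3, dimnames = list(paste0("s", 1:3), paste0("t", 1:4))
  ))
}

test_that("prevalence filtering retains exactly the sufficiently present taxa", {
  tab <- make_toy_table()
  tax <- toy_taxonomy(paste0("t", 1:4))
  out <- filter_taxa(tab, tax, filter_config(min_samples = 2))
  expect_setequal(setdiff(names(out), "sample_id"), c("t2", "t3"))
  expect_equal(out$sample_id, tab$sample_id)
  rep <- filter_report(out)
  expect_equal(rep$n_taxa_out, 2L)
  expect_equal(rep$n_below_prevalence, 2L)
})

test_that("Eukaryota domains and chloroplast labels are removed per configured ranks", {
  tab <- abundance_tibble(matrix(1, 3, 3, dimnames = list(paste0("s", 1:3),
                                                          c("a", "b", "c"))))
  tax <- dplyr::bind_rows(
    toy_taxonomy("a", domain = "Eukaryota"),
    toy_taxonomy("b", order = "Chloroplast"),
    toy_taxonomy("c")
  )
  out <- filter_taxa(tab, tax, filter_config(min_samples = 1))
  expect_setequal(setdiff(names(out), "sample_id"), "c")
  # chloroplast rule restricted to family/genus retains the order-level label
  out2 <- filter_taxa(tab, tax,
                      filter_config(min_samples = 1,
                                    chloroplast_ranks = c("family", "genus")))
  expect_setequal(setdiff(names(out2), "sample_id"), c("b", "c"))
})

test_that("filter_taxa is idempotent and errors on missing taxonomy", {
  tab <- make_toy_table()
  tax <- toy_taxonomy(paste0("t", 1:4))
  cfg <- filter_config(min_samples = 2)
  once <- filter_taxa(tab, tax, cfg)
  twice <- filter_taxa(once, tax, cfg)
  expect_equal(as.data.frame(once), as.data.frame(twice), ignore_attr = TRUE)
  expect_error(filter_taxa(tab, tax[1:2, ], cfg), "missing from taxonomy")
})

test_that("prevalence threshold percentages match the documented study designs", {
  expect_equal(prevalence_threshold_pct(15, 24), 62.5)
  expect_equal(prevalence_threshold_pct(34, 55), 61.8)
  expect_equal(prevalence_threshold_pct(2, 14), 14.3)
})

test_that("aggregation sums counts within identical lineage prefixes and conserves totals", {
  tab <- abundance_tibble(matrix(c(1, 2, 3, 4, 5, 6), 2,
                                 dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
  tax <- dplyr::bind_rows(
    toy_taxonomy("a", phylum = "PhyX", class = "Cla1"),
    toy_taxonomy("b", phylum = "PhyX", class = "Cla2"),
    toy_taxonomy("c", phylum = "PhyY")
  )
  agg <- aggregate_to_rank(tab, tax, "phylum")
  expect_equal(ncol(agg$table) - 1, 2)
  m <- abundance_matrix(agg$table)
  expect_equal(unname(m[, "Bacteria;PhyX"]), c(1 + 3, 2 + 4))
  expect_equal(sum(m), sum(abundance_matrix(tab)))
  # at class level the two PhyX classes stay apart
  agg2 <- aggregate_to_rank(tab, tax, "class")
  expect_equal(ncol(agg2$table) - 1, 3)
  expect_error(aggregate_to_rank(tab, tax, "species"), "rank")
})

test_that("MDM at a rank does not merge across distinct known parents", {
  tab <- abundance_tibble(matrix(1, 2, 2, dimnames = list(c("s1", "s2"),
                                                          c("a", "b"))))
  tax <- relabel_mdm(dplyr::bind_rows(
    toy_taxonomy("a", phylum = "PhyX", genus = "unknown"),
    toy_taxonomy("b", phylum = "PhyY", genus = "unknown")
  ))
  agg <- aggregate_to_rank(tab, tax, "genus")
  expect_equal(nrow(agg$lineage), 2)
  expect_true(all(agg$lineage$is_mdm))
  expect_false(agg$lineage$node_id[1] == agg$lineage$node_id[2])
})

test_that("cross-dataset comparison counts exclusive intersections correctly", {
  a <- toy_taxonomy(c("x", "y"), phylum = c("X", "Y"))
  b <- toy_taxonomy(c("u", "v"), phylum = c("Y", "Z"))
  out <- compare_datasets(list(A = a, B = b), "phylum")
  get_n <- function(combo) out$n_labels[out$combo == combo]
  expect_equal(get_n("A&B"), 1L)  # Y
  expect_equal(get_n("A"), 1L)
  expect_equal(get_n("B"), 1L)

  same <- compare_datasets(list(A = a, B = a), "phylum")
  expect_equal(same$combo, "A&B")
  expect_equal(same$n_labels, 2L)
})

test_that("three-way comparison matches brute-force set algebra and ignores MDM", {
  withr::with_seed(99, {
    pool <- paste0("Phy", 1:8)
    sets <- lapply(1:3, function(i) sample(pool, sample(3:6, 1)))
    names(sets) <- c("A", "MG", "MT")
    taxes <- lapply(sets, function(s) {
      tx <- toy_taxonomy(paste0("t", seq_along(s)), phylum = s)
      # an unknown phylum in every dataset must never count as shared
      dplyr::bind_rows(tx, toy_taxonomy("tu", phylum = "unknown"))
    })
    taxes <- lapply(taxes, relabel_mdm)
    out <- compare_datasets(taxes, "phylum")
    # brute force over every label in the pool
    brute <- table(vapply(pool, function(lbl) {
      paste(names(sets)[vapply(sets, function(s) lbl %in% s, logical(1))],
            collapse = "&")
    }, character(1)))
    brute <- brute[names(brute) != ""]
    for (combo in names(brute)) {
      expect_equal(out$n_labels[out$combo == combo], unname(as.integer(brute[combo])))
    }
    expect_equal(sum(out$n_labels), sum(brute))
    expect_false(any(grepl("MDM", attr(out, "membership")$label)))
  })
})
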