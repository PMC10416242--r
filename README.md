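# microdark

Quantifying the structural role of **microbial dark matter** (MDM) — taxa
lacking a reference classification at one or more taxonomic ranks — in
microbial co-occurrence networks.

Community surveys routinely leave a large fraction of OTUs labeled
"uncultured", "unknown", "NA" or "Incertae Sedis". `microdark` is for
microbial ecologists who want to know whether those unknowns are structurally
dispensable or keystone-like: it relabels them systematically, infers a
co-occurrence network that respects the compositional nature of count data,
screens edges against a permutation null, scores hubs, and measures how much
the network degrades when the unknowns are removed compared with removing an
equal number of known taxa.

## The method

For an OTU table (samples × taxa counts) and seven-rank SILVA-style
lineages:

1. **MDM relabeling.** A lineage whose label at rank *r* matches an
   unknown-classification keyword is relabeled `MDM` at *r* and all lower
   ranks (an unknown order implies an unknown family, genus, species).
2. **Filtering.** Prevalence threshold (nonzero in ≥ `min_samples` samples),
   Eukaryota removal at the domain rank, chloroplast removal at configurable
   ranks; optional aggregation to a rank, with node identity the full
   lineage prefix so unknowns under different parents stay distinct.
3. **Network inference.** Centered log-ratio transform
   `clr(x)_j = log(x_j + 1) − mean_k log(x_k + 1)`, then
   Meinshausen–Bühlmann neighborhood selection: for each taxon *j* the lasso
   regression of `clr_j` on all other taxa; an edge `i—j` when either
   endpoint selects the other (OR rule). The penalty λ is chosen by StARS:
   the densest graph whose edge-selection instability across 20 subsamples
   stays ≤ 0.05.
4. **Edge bootstrap.** Each taxon's abundances are permuted across samples
   (destroying associations, keeping marginals) and the network rebuilt *B*
   times; original edges recurring in more than `⌊αB⌋` replicates are
   removed (at *B* = 5000, α = 0.05: threshold 250).
5. **Hubs.** Kleinberg hub scores (principal-eigenvector centrality on an
   undirected graph, power iteration, max scaled to 1), plus degree,
   betweenness and closeness; top-20 hub tables annotated with lineage.
6. **Degradation.** The MDM-removed network is compared against the
   original and against 100 size-matched removals of random *known* nodes,
   with two-sided Wilcoxon rank-sum tests per centrality metric and
   fragmentation counts.

A synthetic community generator (sparse positive-definite precision matrix →
logistic-normal-multinomial counts; taxonomy strings with controllable
per-rank unknown rates) provides ground truth for end-to-end validation.

## Worked example

```r
library(microdark)

comm <- sim_community(n_samples = 1000, n_taxa = 20, graph_model = "band", seed = 42)
tax  <- relabel_mdm(comm$taxonomy)
ab   <- filter_taxa(comm$abundance, tax, filter_config(min_samples = 2))
net  <- infer_network(ab, seed = 1)
net
#> <mdm_network> 20 nodes, 18 edges (rule OR, penalty 0.2265)
```

The inferred network recovers 18 of the 19 planted band edges. The
permutation bootstrap (here scaled down to B = 200) finds all of them
significant:

```r
sup  <- bootstrap_edge_support(ab, net, B = 200, seed = 2)
filt <- filter_edges(net, sup)
filt
#> <mdm_network> 20 nodes, 18 edges (rule OR, penalty 0.2265)

top_hubs(centrality_profile(filt), tax, k = 5) |>
  dplyr::select(node, hub_score, degree, phylum, genus)
#> # A tibble: 5 × 5
#>   node  hub_score degree phylum genus
#> 1 t015      1          2 MDM    MDM
#> 2 t014      0.966      2 Phy03  MDM
#> 3 t016      0.966      2 Phy02  MDM
#> 4 t013      0.866      2 Phy01  MDM
#> 5 t017      0.866      2 Phy03  MDM
```

The top hub is unclassified from the phylum level down, and all five top
hubs are unknown at the genus level — `mdm_rank_counts()` tabulates this per
rank. Removing the five class-level MDM taxa fragments the network (2 → 4
components) and depresses centrality relative to the original, while
removing five random known taxa (the size-matched null) does not differ
from the MDM-removed network here:

```r
mdm_nodes <- tax$taxon_id[tax$mdm_class]
deg <- degradation_report(filt, intersect(mdm_nodes, filt$nodes),
                          n_reps = 100, seed = 3)
deg$tests
#> # A tibble: 9 × 5
#>   metric      comparison         statistic      p_value stars
#> 1 degree      original vs no_mdm      192  0.0873       ns
#> 2 degree      original vs null      20840  0.000939     ***
#> 3 degree      no_mdm vs null        12524  0.404        ns
#> 4 betweenness original vs no_mdm      254  0.000451     ***
#> 5 betweenness original vs null      24896. 0.0000000210 ****
#> 6 betweenness no_mdm vs null        11844. 0.697        ns
#> 7 closeness   original vs no_mdm       30  0.0000649    ****
#> 8 closeness   original vs null       5462. 0.000000841  ****
#> 9 closeness   no_mdm vs null        10806. 0.791        ns
```

`run_pipeline(demo_config(seed = 1), out_dir = "...")` chains all stages per
rank and writes networks (edge-list TSV + GraphML), edge supports, hub
tables, degradation reports and a JSON manifest with every seed and file
digest; `autoplot()` methods draw the network and the degradation box
plots. A thin shell wrapper lives at `inst/scripts/run-pipeline.R`.

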