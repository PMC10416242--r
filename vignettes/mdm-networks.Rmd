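---
title: "Quantifying microbial dark matter in co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microbial dark matter in co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdark)
library(dplyr)
```

## The problem

A large fraction of the taxa recovered from microbial community surveys —
amplicon, metagenomic or metatranscriptomic — cannot be assigned a reference
classification at one or more taxonomic ranks. These "microbial dark matter"
(MDM) taxa are usually discarded or ignored, yet they may occupy structurally
important positions in the community. `microdark` asks a concrete question:
*when MDM taxa are removed from a co-occurrence network, does the network
degrade more than when an equal number of known taxa are removed?* If yes,
the unknowns are keystone-like and worth prioritizing for characterization.

The package implements the full chain needed to answer that question from an
OTU abundance table and SILVA-style taxonomy strings, plus a synthetic
community generator with known ground truth so every inferential step can be
validated end to end.

## MDM relabeling and filtering

Reference classifiers flag unknowns with a non-uniform vocabulary:
"uncultured", "unknown", "NA", "unknown_family", "Incertae Sedis", empty
labels, and more. `relabel_mdm()` scans each seven-rank lineage from domain
to species and, at the first rank whose label matches a keyword, relabels
that rank *and every rank below it* as `MDM` — an unknown order implies an
unknown family, genus and species. The propagated flags are therefore
downward-monotone by construction, which the test suite property-checks.

Two matching decisions are deliberate. Keywords match as case-insensitive
substrings after rank prefixes (`d__`, `p__`, ...) are stripped and
underscores normalized to spaces, because real lineage strings embed the
markers (`Rhizobiales_Incertae_Sedis`). The exceptions are `"NA"` and the
empty label, which match only as whole labels: as a substring, "na" would
falsely swallow clean names such as *Natronococcus* or *Nodosilineaceae*.
The keyword set is non-exhaustive by nature and user-extensible through
`mdm_keywords(extra = ...)`. Missing trailing ranks in short lineages are
padded with the empty label and hence treated as unassigned — the same
semantics as an explicit `NA`.

`filter_taxa()` applies the three standard pre-network filters: a prevalence
threshold (nonzero counts in at least `min_samples` samples; 2 is typical
for amplicon surveys, majority-of-samples cuts such as 15/24 = 62.5% or
34/55 = 61.8% for deeper designs), removal of Eukaryota at the domain level,
and removal of chloroplast sequences at configurable ranks.

```{r relabel}
tax <- tibble::tibble(
  taxon_id = "t1", domain = "Bacteria", phylum = "Proteobacteria",
  class = "Alphaproteobacteria", order = "unknown", family = "Fam",
  genus = "Gen", species = "Spe")
relabel_mdm(tax) |> select(order:species)
```

## Aggregation and node identity

Networks are built at ranks from phylum to genus. `aggregate_to_rank()` sums
counts over taxa sharing an identical lineage *prefix* down to the target
rank. Node identity is the full prefix, not the rank label alone: "MDM under
Proteobacteria" and "MDM under Cyanobacteria" are distinct nodes. Whether
unknowns should merge or stay separate at an aggregated rank is genuinely
open; we keep them separate because collapsing all unknowns into one
super-node would both misrepresent the count structure (unrelated taxa would
be summed) and make the MDM-removal experiment degenerate (a single node
removal). Domain-level unassigned taxa are kept as MDM rather than dropped,
consistent with treating unassignment as missing knowledge, not absence.

## Network inference

Counts are compositional: sequencing depth is arbitrary, so only relative
information is meaningful. `clr_transform()` maps each sample to the
centered log-ratio scale, `log(x + 1) - mean(log(x + 1))`, the standard
device for making covariance-based inference approximately valid on
compositions; the pseudocount of 1 is the conventional choice for
zero-inflated OTU tables.

`infer_network()` then applies Meinshausen–Bühlmann neighborhood selection:
each CLR column is regressed on all others with an L1 penalty (glmnet's
coordinate descent, predictors standardized, convergence tolerance 1e-6),
a node's neighbors are the predictors with nonzero coefficients, and
directed selections are symmetrized. The `OR` rule (an edge when either
endpoint selects the other) is the default; `AND` is available and is never
denser than `OR`. Edges are unweighted — only the conditional-dependence
support is interpreted.

The penalty is chosen by stability selection (StARS): 20 log-spaced
penalties from the data-driven null penalty (above which every neighborhood
is empty) down to 1% of it; 20 subsamples of size
`min(0.8, 10 * sqrt(n) / n) * n` drawn without replacement; per-penalty edge
instability `2 * mean(p_hat * (1 - p_hat))` over node pairs; and the
smallest penalty (densest graph) whose running-supremum instability stays at
or below 0.05. When no penalty qualifies, the sparsest penalty is returned,
which on association-free data yields an empty or near-empty network — the
correct answer there. Lasso support is not exactly nested along the path, so
edge counts can wiggle locally near saturation; the suite asserts weak
monotonicity (rank correlation, sparse end never denser than dense end)
rather than strict nesting.

## Edge significance by permutation bootstrap

Even a stability-selected network contains edges driven by chance. The
bootstrap filter rebuilds the network `B` times from tables in which every
taxon's abundance vector has been independently permuted across samples —
conserving each taxon's marginal distribution while destroying all
associations — and counts how often each *original* edge recurs. Edges
recurring in more than `floor(alpha * B)` replicates are removed: at the
reference settings `B = 5000`, `alpha = 0.05` the removal threshold is a
count of 250 (251 removes, 250 retains). By default the original selected
penalty is reused in every replicate; re-running stability selection inside
each of thousands of replicates is computationally disproportionate, and
`reuse_penalty = FALSE` is available where the cost is acceptable.

One behavior worth understanding: for a specific pair, the null recurrence
rate is roughly the permuted network's density divided by the number of
pairs. With many taxa this is far below `alpha` and true-signal edges
survive; in very small networks (tens of pairs) it can exceed `alpha`, so on
pure noise *every* edge is removed — which is the desired verdict there. The
calibration test therefore checks consistency of the observed removals with
the binomial prediction from an independently estimated recurrence rate,
not a fixed removal fraction.

## Hub scores and centralities

Hub scores follow the Kleinberg/HITS definition, which on an undirected
graph reduces to principal-eigenvector centrality of the adjacency matrix.
The implementation is a power iteration with a unit diagonal shift:
`A + I` has the same eigenvectors as `A` but a strictly dominant top
eigenvalue, so the iteration also converges on bipartite components (where
iterating on `A^2` would stall in a degenerate eigenspace). The start vector
is all ones, run to tolerance 1e-10, and scores are scaled to max 1. Nodes
outside the dominant component — including isolates — score 0; when several
components tie for the top eigenvalue, the ones start vector weights them
equally. These conventions are frozen in the oracle suite, which compares
the iteration against dense eigendecompositions on thousands of random
graphs.

Classical centralities use the conventions: degree as incident edge count;
betweenness as the unnormalized Brandes pair-dependency sum (validated
against exhaustive shortest-path enumeration); closeness within each
connected component as `(n_c - 1) / sum(d)`, isolates 0. The within-component
closeness convention matters for interpretation: a fragment of two connected
nodes has closeness 1, so fragmentation can *raise* per-node closeness even
as the network disintegrates — component counts should always be read
alongside the closeness distributions. `top_hubs()` ranks nodes by hub score
(ties broken by stable node order) and annotates lineages, reporting how
many of the top `k` (default 20) are MDM at each rank.

## Degradation analysis

`degradation_report()` compares three networks: the original, the network
with all MDM nodes removed (induced subgraph), and `n_reps` (default 100)
null replicates each removing a uniformly random subset of *known* nodes of
the same size — so every null replicate has exactly the node count of the
MDM-removed network, isolating *which* nodes are removed from *how many*.
Per-node degree, betweenness and closeness distributions are compared with
a two-sided Wilcoxon rank-sum test for all three network pairs; null
replicates are pooled into a single distribution per metric, which yields
the single per-pair comparison a summary figure needs (per-replicate testing
would produce `n_reps` p-values per metric with no canonical aggregate). The
rank-sum (unpaired) form is forced by the design: node sets differ across
networks, so no pairing exists. P-values map to the conventional star bands
(`ns` > 0.05 through `****` ≤ 1e-4).

The Wilcoxon implementation uses midranks for ties, exact enumeration of all
group assignments when both groups have at most 8 observations, and the
tie-corrected normal approximation with continuity correction otherwise;
two samples with no variation at all give p = 1 by convention. It is
validated against an independent enumeration oracle and against
`stats::wilcox.test` in the regimes where the latter is exact.

## The synthetic generator

The generator is the package's ground-truth instrument, not a fixture. It
emulates three features of real OTU tables: sparsity-with-zeros, the
compositional constraint, and variable sequencing depth.

* **Structure**: a sparse symmetric positive-definite precision matrix over
  taxa (band, hub or Erdős–Rényi support; off-diagonal magnitudes 0.25–0.45;
  band/hub entries negative, i.e. positive partial correlation, the typical
  co-occurrence signal). The diagonal is loaded uniformly until the
  condition number reaches `condition_target` (default 10), and the loading
  is recorded.
* **Counts**: logistic-normal-multinomial — latent Gaussian with covariance
  equal to the inverse precision, softmax to a composition, multinomial draw
  at a per-sample depth uniform on `depth_range` (default 2,000–10,000,
  an amplicon-scale range). This, rather than a Dirichlet-multinomial, is
  the model whose CLR-scale dependence structure the MB estimator targets,
  so recovery experiments measure the estimator, not a model mismatch.
* **Taxonomy**: hierarchically consistent clean lineages with each rank's
  label independently replaced by an unknown keyword at a per-rank rate.
  The default profile `(0.03, 0.06, 0.15, 0.30, 0.45, 0.70, 0.97)` rises
  steeply with depth, approximating what amplicon surveys of poorly
  characterized communities report (a few percent unassigned at domain,
  a large majority unknown at genus and species).

What the generator does *not* emulate: taxon-specific abundance means (the
latent mean is zero, so taxa are exchangeable in abundance), overdispersion
beyond the logistic-normal, chimeras and classification error, or temporal
sample structure. Recovery results therefore say the estimator works when
its model holds at realistic sparsity and depth — not that any particular
real dataset satisfies that model.

Under the reference validation conditions — band graph, 20 taxa, 1,000
samples (the 50-samples-per-taxon regime) — the seed-pinned suite requires
edge-recovery F1 ≥ 0.8; on independence structure it requires an (almost)
empty selected network.

## Numerical and reproducibility choices

* Coordinate-descent tolerance 1e-6 (glmnet `thresh`); power-iteration
  tolerance 1e-10 with all-ones start; CLR row sums checked to 1e-8.
* Every stochastic operation takes an explicit seed; multi-replicate
  operations derive child seeds from the master seed by counter, and
  `run_pipeline()` records all stage seeds, the full configuration and
  per-file MD5 digests in a JSON manifest. Two runs with the same
  configuration and seed produce byte-identical artifacts (the manifest's
  timestamp excepted).
* Ties in hub ranking break by stable node order; degenerate rank-sum inputs
  give p = 1; an edgeless network yields all-zero hub scores with a warning
  rather than an error.
* Test and demo problem sizes are deliberately modest (tens of taxa,
  hundreds of samples, B = 200, 25–100 null replicates); they were chosen so
  the full validation suite exercises every stage at meaningful power while
  remaining quick to run. Reference defaults (`B = 5000`, 100 replicates,
  top 20) remain the production settings in `default_config()`.

## Known limitations

* Inference quality degrades when taxa far outnumber samples; the package
  reports instability curves so that regime is visible, but no warning fires
  automatically.
* The bootstrap filter tests edge recurrence under a marginal-preserving
  null; it is not a per-edge p-value with FDR control, and none is applied.
* Aggregated-rank networks inherit the aggregation convention: distinct-MDM
  nodes are real modeling choices, and different conventions would change
  hub tables at those ranks.
* The end-to-end pipeline runs ranks independently; no multiple-testing
  correction is applied across ranks or metrics.

## A complete run

```{r pipeline, eval = FALSE}
res <- run_pipeline(demo_config(seed = 1), out_dir = "microdark-demo")
res$ranks$phylum$top_hubs
autoplot(res$ranks$phylum$degradation)
```
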