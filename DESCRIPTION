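Package: microdark
Title: Quantifying Microbial Dark Matter in Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the structural role of unknown taxa
    ("microbial dark matter") in microbial co-occurrence networks. Relabels
    taxa whose SILVA-style lineages carry unknown-classification keywords,
    filters and aggregates OTU abundance tables, infers compositional
    association networks by Meinshausen-Buhlmann neighborhood selection with
    StARS penalty selection, screens edges with a per-taxon permutation
    bootstrap, scores Kleinberg hubs and classical centralities, and measures
    network degradation after removal of unknown taxa against a size-matched
    random-removal null. Includes a synthetic community generator with known
    ground-truth association structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
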