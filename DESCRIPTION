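Package: sarcoscreen
Title: Drug-Screen Normalization, Synergy Scoring, Hub-Gene Consensus,
    Target-Filter Cascades and Splicing Screens for Osteosarcoma-Style
    Multi-Omic Drug Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native reimplementation of the computational core of
    a multi-omic osteosarcoma drug-discovery workflow: 384-well viability
    screen normalization and hit calling, four-parameter logistic
    dose-response fitting with sub-IC50 combination-dose selection, Bliss
    Independence and Chou-Talalay drug-synergy scoring, ten-measure
    network-centrality consensus hub-gene detection on protein-protein
    interaction graphs, a tumor-specific-gene and surface-target
    differential-expression filter cascade (CPM + Wilcoxon +
    Benjamini-Hochberg), and a percent-spliced-in alternative-splicing
    screen with event classification, differential and heterogeneity tests.
    Ships seeded synthetic-data generators that emulate every input the
    pipeline consumes, so the full workflow is testable without access to
    the original screen or sequencing data.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
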