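Package: fibronet
Title: Tissue-Stratified Differential Expression and Protein Interaction
    Network Centrality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for tissue-stratified transcriptomic
    systems biology: empirical-Bayes moderated-t differential expression
    on two-group log2 expression matrices, construction of scored
    protein-protein interaction networks by confidence-filtered shell
    expansion with iterative re-seeding, hub/bottleneck/switch (HBS)
    centrality classification, hypergeometric over-representation
    analysis with Benjamini-Hochberg FDR at two stringency tiers, and
    cross-tissue overlap statistics. Includes a seeded synthetic-data
    module (two-cohort expression matrices with planted fold changes,
    preferential-attachment interaction networks with a planted hub,
    and annotation sets with a planted enriched term) so the whole
    pipeline is testable end to end without external downloads.
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
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
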