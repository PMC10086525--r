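Package: magsig
Title: Conserved Immune-Aging Signatures via MAG Rank Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering transcriptional and chromatin
    signatures of aging that are conserved across mouse strains and
    immune tissues. Provides per-stratum negative-binomial GLM age
    association for count features, magnitude-of-association (MAG)
    rank aggregation across strains and tissues, preranked gene set
    enrichment analysis with a permutation null, principal variance
    component analysis, hypergeometric module enrichment, ATAC-seq
    footprint statistics (consensus peaks, purity filtering,
    enrichment in opening and closing peaks, aggregate cut-site
    profiles), and linear age trends for cell-type composition. A
    seeded synthetic-data generator emulates the two-strain,
    four-tissue study design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    edgeR,
    lme4,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
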