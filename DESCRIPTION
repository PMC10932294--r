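Package: ptenet
Title: Proteome-Driven Metabolic Flux and Network Analysis for Post-Traumatic Epilepsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for systems-level analysis of chronic
    post-blast traumatic brain injury proteomes. Calls differentially
    expressed proteins from label-free LC-MS/MS intensity tables
    (total-intensity normalization, peptide-to-protein rollup, technical
    replicate averaging, Welch t-tests with Benjamini-Hochberg adjustment,
    detection sentinels), predicts metabolic shifts by flux balance
    analysis of a stoichiometric model with fold-change-constrained
    reaction bounds under a biomass-maintenance objective, ranks candidate
    drug targets in a confidence-thresholded protein-protein interaction
    network by weighted multi-centrality scores and PageRank, screens
    single-channel EEG traces for electrographic seizure candidates, and
    generates synthetic fixtures with planted structure for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    pracma,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
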