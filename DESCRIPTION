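Package: soilnet
Title: Assembly Processes, Co-Occurrence Networks and Stability of Soil
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for amplicon-derived count tables: rarefaction
    and prevalence filtering, alpha diversity and weighted UniFrac beta
    diversity with PCoA and PERMANOVA, beta nearest taxon index (betaNTI)
    classification of community assembly processes under a tip-shuffling
    phylogenetic null model, Spearman co-occurrence network construction
    with Benjamini-Hochberg corrected thresholds, within-module (Zi) and
    among-module (Pi) connectivity with keystone-role classification, and
    network stability analysis by robustness simulation and efficiency-based
    vulnerability. Includes a synthetic amplicon-data generator with planted
    correlation modules, hub taxa and a phylogenetically conserved
    habitat-filtering signal, so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phyloseq,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
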