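Package: ciscogen
Title: Genomic Resilience Analysis for Isolated Cold-Water Fish Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the genomic resilience of small, isolated
    cold-water fish populations (inland lake cisco and similar lacustrine
    salmonids). Implements RAD/Rapture genotype filtering with an HDPlot-style
    paralog screen, population-genetic diversity and differentiation statistics
    (Weir-Cockerham theta, Nei's D_A, neighbour-joining trees, hierarchical
    AMOVA, Mantel tests, LD-based effective population size), deleterious-
    mutation load metrics from effect-score classification, multi-copy MHC
    amplicon haplotype calling with resampling rarefaction and a Nei-Gojobori
    codon Z-test, oxythermal habitat metrics (TDO3, COSD, habitat thickness and
    volume) from daily lake temperature and dissolved-oxygen profiles, and a
    correlation stage (collinearity pruning, redundancy analysis, lmg relative
    importance) linking genetic metrics to spatial and environmental
    predictors. Ships seeded synthetic-data generators with known truth for
    every input so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    broom,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    vegan
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
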