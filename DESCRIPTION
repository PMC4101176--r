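Package: aimeval
Title: Evaluating Ancestry-Informative Marker Panels by Simulation and Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how SNP-panel size and marker informativeness
    determine the accuracy of individual genome-ancestry estimates. Simulates
    structured source populations under the Balding-Nichols model together
    with artificial admixed genomes, estimates individual admixture
    proportions by maximum likelihood (supervised and unsupervised EM, with
    cross-validation choice of the number of clusters), scores markers by
    pairwise Weir-Cockerham F_ST and locus-specific branch lengths (LSBL),
    selects LSBL-balanced marker panels, and runs resampling experiments
    (random-SNP panels, pre-designed panels, population sub-sampling) that
    summarise ancestry recovery as means, standard deviations, confidence
    intervals and errors relative to a genome-wide reference. Reads and
    writes PLINK PED/MAP text and a TSV genotype-matrix dialect, and provides
    identity-by-state similarity with two-dimensional principal-coordinate
    maps for structural checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
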