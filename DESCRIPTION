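Package: ecsig
Title: Behavioral Emotionality Scoring and PBMC Spectral-Count Proteomics
    for Antidepressant and ECS Response Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rodent antidepressant-response studies that
    combine a behavioral test battery with label-free spectral-counting
    proteomics of peripheral blood mononuclear cells. Computes composite
    behavioral emotionality z-scores against a vehicle control group,
    classifies treated animals as responders or non-responders from the
    individual percent change in score, and provides normality-gated location
    tests plus Kaplan-Meier/log-rank inference for censored feeding latencies.
    The proteomic arm filters peptide-spectrum matches by E-value rules,
    groups proteins sharing peptides into groups and subgroups, assembles
    spectral-count matrices, tests differential abundance with per-protein
    Poisson regression and Benjamini-Hochberg adjustment, calls directions
    from pairwise contrasts, and summarises results with Euclidean/UPGMA
    biclustering and principal component analysis with per-group bivariate
    normal densities. Synthetic cohort and count-matrix generators with known
    ground truth make every stage testable without raw mass-spectrometry data.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
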