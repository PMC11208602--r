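Package: rocrestrict
Title: Restricted ROC Curves for Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dataset restriction for biomarker discovery. Splits samples at
    every observed biomarker value into high and low parts, computes
    restricted ROC curves and sample-size standardised restricted AUCs
    (rzAUC), finds the optimal restriction and its informative range,
    assigns permutation p-values, evaluates classification on classifiable
    samples only, and feeds restriction-aware sentinel-encoded features into
    random-forest models. Also provides a generative flow cytometry
    simulator: a hierarchical gating tree with a Dirichlet model for leaf
    population proportions and per-leaf Gaussian antigen distributions, with
    precision-preserving injection of disease-associated effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    ranger,
    mclust
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
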