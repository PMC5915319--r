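Package: ccce
Title: Common Environmental Effects on Immune Cell Subfunctions from Twin
    Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects common-environment effects on immune-cell subfunctions
    from twin-cohort multicolor flow-cytometry data.  Cell-subpopulation
    frequency traits are age-adjusted and decomposed into additive-genetic,
    common-environment and unique-environment variance fractions with the
    Falconer formula; the common-environment fraction (c2) is then regressed
    on the +1/-1 marker signatures of the subpopulations with an elastic net
    tuned by K-fold cross-validation, and significance is assigned by a
    permutation null on the cross-validated prediction error, with
    Benjamini-Hochberg false-discovery-rate control across cell-type
    datasets.  Includes a seeded twin-cohort simulator with planted ACE
    variance components for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
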