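Package: serialdep
Title: Serial Dependence and Contrast-Dependent Aftereffects in Orientation Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits models of serial effects in orientation
    perception under contrast manipulation. Provides a synthetic-experiment
    generator for a three-group adaptor/test design (unimodal and bimodal
    adaptor distributions, high- and low-contrast test Gabors), a descriptive
    piecewise-linear serial-history model of psychometric midpoint shifts,
    and a Bayesian observer built on a bank of von Mises orientation channels
    with contrast-dependent gain, per-stimulus adaptation with time-based
    recovery, slow prior integration, and an ROC-based decision rule.
    Includes joint maximum-likelihood fitting, AIC/BIC and likelihood-ratio
    model comparison, and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
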