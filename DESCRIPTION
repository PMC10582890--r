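Package: polyscreen
Title: Screening Performance Calculators for Polygenic Risk Scores
Version: 1.0.0
Authors@R:
    person("Polyscreen", "Developers", email = "polyscreen@example.org",
           role = c("aut", "cre"))
Description: Converts published polygenic risk score performance metrics
    (odds ratio or hazard ratio per standard deviation, AUC, C-index) into
    screening-relevant quantities under a two-Gaussian equal-variance model:
    detection rates for a chosen false positive rate, likelihood ratios
    (threshold, centile density-ratio, and quantile area-ratio forms), and
    Bayesian odds of becoming affected. Includes population risk
    stratification tables, number-needed-to-genotype and events-prevented
    calculators, a two-stage screening flow model, a catalog-style
    performance-table ingestion pipeline with plausibility filters, a
    synthetic cohort and mock-catalog generator for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
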