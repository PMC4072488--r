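Package: hrscan
Title: Cutpoint Scans and Spline-Smoothed Hazard Ratios for ICU Survival Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects nonlinear and threshold relationships between continuous
    risk factors (glycated hemoglobin, body mass index) and in-hospital
    mortality in intensive-care cohorts. Implements a dichotomization cutpoint
    scan of adjusted Cox hazard ratios, smoothed with a four-knot restricted
    cubic spline and equipped with Bonferroni-corrected simultaneous
    confidence bands, together with the supporting machinery: a maximum
    partial-likelihood Cox engine (Breslow and Efron ties), Kaplan-Meier and
    log-rank estimation, covariate-adjusted survival curves by BMI strata,
    descriptive cohort tables with ADA glucose-tolerance and WHO BMI
    categories, and a calibrated synthetic ICU-cohort generator for
    validation by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    survival,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
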