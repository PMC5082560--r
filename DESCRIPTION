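Package: mroverlap
Title: Weak-Instrument Bias and Type 1 Error in Two-Sample Mendelian
    Randomization with Sample Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic calculators for the bias and Type 1 error inflation of
    instrumental-variable estimates in Mendelian randomization when the
    exposure-association and outcome-association samples partially overlap.
    Includes instrument-strength diagnostics (first-stage F statistics,
    F/R-squared conversions, one-sided confidence intervals for the F
    parameter via noncentral-F inversion), instrumental-variable estimators
    (ratio, split-sample two-stage least squares, inverse-variance weighted
    and equally weighted allele-score analyses from summarized data) for
    continuous and binary case-control outcomes, data-generating models for
    simulation, and a Monte Carlo harness that validates the analytic
    formulae against simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
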