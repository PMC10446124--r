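Package: rcsimex
Title: Measurement Error Correction by Regression Calibration and
    Simulation-Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correction and sensitivity analysis for classical (random)
    measurement error in a continuous exposure in linear and logistic
    regression. Implements regression calibration and simulation-
    extrapolation (SIMEX), pooled within-individual estimation of the
    measurement-error variance from replicate measurements, percentile
    bootstrap confidence intervals, a Monte Carlo simulation-study engine
    with bias, mean squared error, coverage, and their Monte Carlo standard
    errors, and a probabilistic (quantitative) bias-analysis framework that
    places a prior distribution on the measurement-error variance for
    settings without validation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
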