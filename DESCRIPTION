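Package: svcpois
Title: Semi-Varying Coefficient Conditional Poisson Models for Daily Helpline Call Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a first-order autoregressive conditional Poisson time-series
    model with a smoothly time-varying carryover coefficient, parametric
    day-of-week modifiers of the carryover, and an immigration term driven by
    day-of-week effects and television advertising weight (TARPs). Estimation
    is by profile backfitting between a local-linear kernel smoother and
    identity-link quasi-Poisson estimating equations. Includes an
    overdispersion-adjusted nonparametric residual bootstrap for standard
    errors and pointwise confidence bands, goodness-of-fit diagnostics
    (Poisson deviance R-squared, Pearson residuals, a regression-based
    overdispersion test), a five-model mean-square-error comparison, and a
    synthetic-data generator emulating smoking-cessation helpline demand under
    pulsed advertising campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
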