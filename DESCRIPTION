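Package: dynfc
Title: Sliding-Window Dynamic Functional Connectivity and Longitudinal
    Cognition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies temporal variability of resting-state functional
    brain networks from parcellated BOLD time series using a sliding-window
    coefficient-of-variation statistic, tests it against a multivariate
    phase-randomization null model that preserves stationary connectivity
    and autocorrelation, derives regression-based normative change scores
    for neuropsychological tests, and links connectivity change to
    cognitive change with Type-III repeated-measures analyses of
    covariance. Includes a synthetic-cohort generator producing BOLD-like
    autocorrelated signals with controllable time-varying coupling and
    cognitive scores with configurable group-specific slopes, so the full
    pipeline is testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
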