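Package: hurstpls
Title: Fractal Brain Dynamics and Psychopathology via Hurst Exponents and
    Behavioral Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating long-range temporal dependence in parcellated
    BOLD fMRI time series to dimensional psychopathology. Implements detrended
    fluctuation analysis (DFA) estimation of the Hurst exponent with a
    frequency-constrained window scheme and per-fit goodness diagnostics,
    behavioral partial least squares (PLS) on the Hurst-by-factor-score
    cross-block covariance with optional survey sampling weights, permutation
    significance and bootstrap stability, per-subject pattern scoring,
    variogram-matched spatially autocorrelated surrogate maps for spin-style
    map tests, meta-analytic term and activation axis analyses, block-level
    Hurst contrasts, signal-detection sensitivity, weighted correlations,
    Fisher confidence intervals, and stratified k-fold cross-validation. A
    synthetic cohort generator plants known latent structure (true Hurst
    fields, factor loadings, task-block suppression, behavior coupling,
    stratified sampling weights) so every stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
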