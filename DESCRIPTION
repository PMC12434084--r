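Package: wemc
Title: Weekly Exceedance in Mortality Counts: Forecasting, Indicator
    Matrices, and Exceedance Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase pipeline for probabilistic analysis of weekly
    cause-specific mortality counts. Phase I fits per-cause harmonic
    (Fourier) seasonal regressions with linear trend and forecasts a fixed
    horizon. Phase II combines observed and forecast panels into a binary
    weekly-exceedance indicator matrix and estimates per-cause binomial
    exceedance probabilities (the weekly change in mortality indicator,
    WCMI), with a chi-square/Cramer's V independence check. Phase III
    computes single, joint, and conditional event probabilities for the
    binomial indicators, and the distribution of sums of independent
    non-identical binomials via exact convolution and a lattice
    saddlepoint (Lugannani-Rice) approximation, plus validation
    statistics comparing observed- and forecast-window estimates. A
    synthetic-data generator produces CDC-like correlated weekly count
    panels for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
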