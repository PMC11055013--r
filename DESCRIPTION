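Package: weighttraj
Title: Classify Irregular Body-Weight Trajectories by Sequential Polynomial Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying irregular, self-reported longitudinal
    body-weight series into discrete trajectory patterns. Fits nested linear,
    quadratic and cubic regressions to each participant's series, selects the
    optimal model by a 5% relative change in adjusted R-squared, derives
    analytic landmarks (quadratic nadir, cubic vertices via the derivative
    discriminant) and applies a sequential decision tree to assign one of
    seven trajectory patterns. Includes a 14-day early-prediction multinomial
    logistic model with odds-ratio reporting, per-participant k-fold
    cross-validation, classification-threshold sensitivity analysis,
    growth-chart style percentile curves, and a synthetic cohort simulator so
    the whole pipeline is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
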