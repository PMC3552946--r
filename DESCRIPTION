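Package: metapi
Title: Prediction Intervals and Rectangle-Style Forest Plots for
    Random-Effects Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse-variance meta-analysis under fixed-effect and
    random-effects models with DerSimonian-Laird between-study variance,
    Cochran's Q and I-squared heterogeneity statistics, and the t-based
    95 percent prediction interval on k - 2 degrees of freedom. Forest
    plots display the prediction interval as a dedicated rectangle row,
    visually distinct from the summary diamond, alongside the competing
    hollow-diamond and extended-diamond styles. Includes a Monte-Carlo
    simulator for the random-effects hierarchy to validate coverage of
    the prediction interval, helpers to compute prediction intervals
    from published summary numbers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
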