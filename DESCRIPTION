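Package: elitemort
Title: Comparative Mortality of Elite Cohorts Against Period Life Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare the mortality of an elite cohort (for example
    national politicians) with the general populations they belong to over long
    historical periods. Reads and interpolates HMD-style period life tables,
    expands individual follow-up into person-year (Lexis) slices starting at
    office entry to avoid immortal time bias, computes yearly standardised
    mortality ratios with pro-rata first-year exposure, smooths SMR trends with
    Bayesian Poisson offset models selected by DIC, performs direct
    standardization with World Standard Population weights, fits left-truncated
    Gompertz proportional-hazards models on the age scale in consecutive
    ten-year windows to estimate remaining life expectancy at age 45, and
    derives gender-pooled life-expectancy gaps with bootstrap confidence
    intervals. A synthetic-data generator with known ground truth (hazard
    ratios, SMR curves, life-expectancy gaps) makes every pipeline stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    mgcv,
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    flexsurv,
    ggplot2
Config/testthat/edition: 3
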