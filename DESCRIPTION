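Package: heatbirth
Title: Heat-Wave Exposure and Early Birth via Time-Stratified Case-Crossover Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating acute associations between heat-wave exposure
    and preterm or early term birth with a time-stratified case-crossover design.
    Converts gridded daily temperatures to ZIP Code Tabulation Area (ZCTA) series,
    computes relative-threshold heat-wave metrics over a four-day exposure window
    (consecutive hot days and average degrees above threshold), assembles
    month-by-weekday matched case-crossover strata restricted to the warm season,
    adjusts for the daily probability of birth among ongoing pregnancies at risk,
    fits conditional logistic regression by Newton-Raphson on the exact
    one-case-per-stratum conditional likelihood, pools state-specific estimates by
    fixed-effect inverse-variance weighting, and tests between-stratum
    heterogeneity. A synthetic-data generator with known multiplicative heat
    effects supports end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    lubridate,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    survival,
    jsonlite,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
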