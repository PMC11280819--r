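Package: aquarisk
Title: Water-Quality Indexing, Eutrophication Scoring, Probabilistic
    Health-Risk Assessment and Geodetector Source Apportionment for
    Drinking-Water Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for assessing surface
    drinking-water sources from routine monitoring tables. Computes a
    weighted water-quality index (WQI) with configurable normalization
    tables, the logarithmic power-function universal eutrophication index
    (EI) with trophic-grade classification, deterministic and Monte Carlo
    oral-ingestion health-risk assessment for heavy metals (average daily
    dose, carcinogenic risk and hazard quotient for adults and children),
    and geodetector source apportionment (factor detector q-statistic,
    continuous-covariate discretization including exact Jenks natural
    breaks, and the five-category two-factor interaction detector).
    Includes a synthetic-data generator that emulates a seasonal
    multi-site monitoring campaign with spatially structured covariates
    and planted stratum effects of analytically known explanatory power,
    plus Spearman correlation and varimax-rotated principal-component
    summaries for source grouping.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
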