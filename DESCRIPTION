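Package: cfrisk
Title: Counterfactual Risk Estimation for Prediction Models Using Trial and
    Observational Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits models tailored to counterfactual outcomes and estimates the
    counterfactual risk (expected loss) of an arbitrary prediction model in the
    population underlying an observational study, using data from the
    observational study, a companion randomized trial, or both. Implements
    outcome-model, inverse-probability-weighted, and doubly robust estimators
    for the observational, transportability, and joint analyses; stratified
    nonparametric bootstrap inference and benchmarking of the observational
    against the transportability estimate; and a synthetic-data generator with
    knobs that selectively violate the conditional-exchangeability assumptions,
    with oracle truths for bias, efficiency, and coverage studies.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
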