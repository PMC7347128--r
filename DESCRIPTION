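Package: blight311
Title: Identify Urban-Blight-Related Records in Municipal 311 Service-Request Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A natural-language-processing pipeline for measuring urban blight
    from municipal 311 service-request exports. Builds a class-exclusive token
    lexicon from manually labelled calls, scores each call by its count of
    distinct lexicon tokens, classifies calls with logistic regression models
    that add borough and responsible-agency covariates, validates the
    classifier with confusion-matrix metrics and Cohen's kappa, and aggregates
    predictions to census tracts for convergent-validity correlation against
    residential and commercial vacancy measures. Includes a synthetic-data
    generator with known ground truth so every stage is testable without
    large downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
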