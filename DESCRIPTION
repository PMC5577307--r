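Package: telopac
Title: Parental Age Effects on Offspring Relative Telomere Length
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for testing maternal and paternal
    age-at-conception effects on offspring relative leukocyte telomere
    length (RTL) in a wild sheep population. Provides a synthetic-data
    generator for phenotypes and raw qPCR amplification curves with the
    study's crossed random-effects structure; qPCR plate processing with
    baseline correction, window-of-linearity efficiency and Cq
    estimation, triplicate and efficiency quality control, and
    calibrator-normalised efficiency-corrected RTL computation; crossed
    random-intercept linear mixed models with likelihood-ratio tests for
    linear and quadratic parental-age terms; and a Monte-Carlo power
    analysis with slope-to-correlation effect-size conversion.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
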