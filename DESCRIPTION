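Package: sexsignal
Title: Sex-Stratified Disproportionality Analysis for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sex-stratified pharmacovigilance signal detection on
    individual case safety reports (ICSRs). Implements the Bayesian
    information component (IC) with exact gamma-posterior credibility
    intervals, the reporting odds ratio and proportional reporting ratio
    comparators, per-sex stratified contingency counting, classification of
    sex-difference patterns across adverse drug reactions, and a fully
    specified synthetic ICSR generator with planted sex-specific signals so
    that every stage of the pipeline can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
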