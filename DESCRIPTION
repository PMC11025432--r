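Package: mltcassign
Title: Disease Cluster Assignment Strategies for Multiple Long-Term Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning disease clusters to people with multiple
    long-term conditions (MLTC) and evaluating how well different assignment
    strategies explain one-year health outcomes. Implements seven strategies
    (threshold at one, two or three diseases per cluster; modal; majority;
    count; proportion), assignment-pattern summaries, median age-at-onset
    profiles per disease and per cluster, logistic-regression comparison of
    strategies against a disease-level reference model using AIC, and
    within- versus between-cluster dispersion of adjusted odds ratios. A
    synthetic electronic-health-record cohort generator with known
    disease-level effects supports end-to-end testing and effect-recovery
    checks without access to restricted primary-care data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
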