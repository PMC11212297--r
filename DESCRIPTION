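Package: ruralni
Title: Noninferiority and Power Analysis for Rare Surgical Adverse Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing rare adverse-event outcomes between an
    intervention arm (for example rural surgical facilities) and a control arm
    (referral facilities) under heavy class and arm imbalance. Provides Firth
    penalized logistic regression with Wald and penalized likelihood-ratio
    tests at arbitrary point nulls, noninferiority testing with a
    half-margin-of-error rule for selecting the margin, cumulative
    comorbidity-level risk stratification with E-value sensitivity analysis,
    a Monte Carlo power and minimum-sample-size engine, and a synthetic
    patient-cohort simulator with a 30-day coded-visit adverse-event window.
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
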