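Package: pvsignals
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for pharmacovigilance signal detection
    over spontaneous reporting system databases such as FAERS and JADER.
    Ingests the quarterly dollar-delimited FAERS tables and JADER-style CSV
    tables into a unified deduplicated case store, normalizes drug names to
    ingredients and MedDRA preferred terms to composite neurological
    immune-mediated adverse event categories, and computes four
    disproportionality statistics per drug-event pair: the reporting odds
    ratio (ROR), the proportional reporting ratio (PRR) with Pearson
    chi-squared, the Bayesian confidence propagation neural network (BCPNN)
    information component, and the multi-item gamma Poisson shrinker (MGPS)
    empirical-Bayes geometric mean. Also provides descriptive cohort
    analytics (demographics, annual reporting trend with Spearman
    correlation, time to onset, mortality rates, severity association) and a
    ground-truthed synthetic spontaneous-report generator with planted
    signals for end-to-end validation.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
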