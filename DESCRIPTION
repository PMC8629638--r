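Package: casemixr
Title: Case-Mix Grouping and Payment Control for Inpatient Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating diagnosis-related-group (DRG)
    style case-mix classifications from inpatient claims data, motivated by
    cost control for cerebrovascular disease (ICD-10 I60-I69) hospitalizations.
    Provides a seeded synthetic claims generator, auditable data-cleaning
    filters, Kruskal-Wallis single-factor screening, blockwise stepwise linear
    regression, a from-scratch CHAID (chi-squared automatic interaction
    detection) tree with F-test and binned chi-squared modes, a declarative
    DRG rule engine with two shipped cerebrovascular rule sets (with and
    without length of stay), per-group case-mix metrics (coefficient of
    variation, relative weight, P75 + 1.5 IQR cost limit, outlier excess), and
    a fee-for-service versus DRG payment simulation across stepped control
    intensities.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
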