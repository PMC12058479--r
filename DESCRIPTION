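Package: faersignal
Title: Disproportionality Signal Detection and Risk Modelling for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pharmacovigilance pipeline for FAERS-style spontaneous
    adverse-event reports, built around the drug-induced cataract case study:
    parsing and cleaning of quarterly "$"-delimited report files
    (deduplication by case version, primary-suspect drug restriction,
    demographic plausibility filters), reporting odds ratio (ROR)
    disproportionality screening with Fisher exact tests and Bonferroni
    correction, LASSO-then-multivariate logistic risk-factor modelling with
    ROC evaluation, time-to-onset summaries, and descriptive baseline
    reports. Includes a seeded synthetic report generator with a ground-truth
    ledger (injected per-drug odds ratios, duplicate case versions,
    missing and implausible demographics) for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
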