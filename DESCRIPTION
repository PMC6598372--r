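Package: methpanel
Title: Cumulative Urine DNA Methylation Panel Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for semi-quantitative methylation-specific
    qPCR biomarker panels measured in urine DNA. Transforms quantification
    cycle (Cq) values into 0-15 methylation signals, scores each sample by
    its number of positive markers and average methylation, evaluates
    diagnostic performance (sensitivity, specificity, PPV, NPV with Wald
    confidence intervals) at every panel threshold, computes empirical ROC
    curves and Mann-Whitney AUC with half-credit ties, compares risk
    grading groups and paired post-DRE/first-void samples, and generates
    reproducible synthetic cohorts with the statistical structure of a
    prostate-cancer screening study.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
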