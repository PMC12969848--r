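Package: burnagree
Title: Agreement and Non-Inferiority Analysis for Region-Level Burn Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnostic accuracy and agreement studies of burn
    assessment in which several raters (an automated model, a group of
    emergency physicians, and an expert reference panel) score the same
    burn region-cases for total body surface area (TBSA, percentage
    points) and a three-level ordinal depth class. Implements expert-panel
    and physician-group consensus adjudication, paired non-inferiority
    testing of region-level TBSA error via the Hodges-Lehmann estimator
    with a patient-level cluster bootstrap, and a full secondary battery:
    quadratically weighted kappa, Lin's concordance correlation
    coefficient, Bland-Altman limits of agreement, two-way random-effects
    intraclass correlation, calibration regression, tolerance bands,
    ROC/AUC with DeLong comparison, confusion-matrix reconstruction from
    marginal totals, subgroup and image-quality sensitivity analyses. A
    synthetic cohort generator reproduces the clustered multi-rater
    structure of such studies so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
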