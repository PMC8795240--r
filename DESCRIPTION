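Package: ihscreen
Title: Interaction-Heterogeneity Screening of Structured and Unstructured EHR Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how coded (structured) and clinician-note-derived
    (unstructured) electronic health record features interact with respect to a rare
    clinical outcome. Simulates longitudinal EHR cohorts with known ground truth,
    applies first-occurrence feature construction under inclusion and index-event
    censoring rules, fits an additive naive-Bayes odds-ratio risk score and a
    balanced random forest benchmark, and screens structured-unstructured feature
    pairs with stratified contingency tables: chi-squared association tests per
    cohort, Woolf homogeneity of odds ratios (interaction heterogeneity), joint-risk
    summaries, and Bayes posterior outcome probabilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    rpart,
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
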