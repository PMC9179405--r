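Package: cohortpath
Title: Claims-Based Cohort Construction and Care-Pathway Mining for Early Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds early breast cancer cohorts from longitudinal
    reimbursement-claims tables (hospital diagnoses and procedures,
    outpatient drug dispensings, in-hospital costly-drug administrations).
    Applies an ordered battery of ten inclusion/exclusion filters with full
    attrition accounting, detects treatment modalities (surgery,
    radiotherapy, chemotherapy, endocrine therapy, anti-HER2 targeted
    therapy) inside temporal windows anchored on the index surgery,
    classifies settings and regimens, dates the diagnosis from diagnostic
    procedures, infers tumour subtype from treatment exposure, derives
    canonical care pathways, and reports descriptive summaries,
    critical-bandwidth multimodality tests, and Kaplan-Meier survival.
    Ships a seeded synthetic-claims generator with per-patient ground truth
    so every stage is testable without access to a restricted national
    database.
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
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
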