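Package: memtrack
Title: Longitudinal Blood Transcriptomic Biomarkers of Memory: Discovery,
    Prioritization and Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering, prioritizing and testing
    blood gene-expression biomarkers that track short-term memory and
    predict future cognitive decline in longitudinal psychiatric cohorts.
    Implements within-subject differential-expression (DE) and
    absent-present (AP) scoring of probesets against memory-retention
    changes, Convergent Functional Genomics (CFG) prioritization against a
    structured literature-evidence database with capped line-of-evidence
    weights, state prediction of low-memory visits by ROC analysis, trait
    prediction of future positive neuropsychological testing by Cox
    regression with cross-sectional and longitudinal composite measures,
    Convergent Functional Evidence (CFE) tabulation, and enrichment
    statistics (probeset survival folds, circadian clock-gene enrichment).
    Includes a seeded synthetic longitudinal cohort generator with planted
    phenotype-tracking probesets and time-to-event outcomes so the whole
    pipeline can be exercised and validated without access to clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
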