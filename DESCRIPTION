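Package: modytree
Title: Biomarker Decision Trees for Prioritising HNF1A MODY Genetic Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and evaluating sequential biomarker decision
    trees that separate HNF1A MODY (maturity-onset diabetes of the young due
    to HNF1A mutations) from GCK MODY, type 1 and type 2 diabetes. Provides
    tie-aware C-statistics with DeLong variance and paired AUC tests, logistic
    composite biomarker indices, C-statistic-gated forward marker selection
    with group peeling, Youden threshold selection, cascade classification
    with confusion-matrix reporting, and a synthetic four-group cohort
    simulator whose marker distributions are anchored to published group
    summaries (means with SDs; medians with quartiles, including a C-peptide
    detection floor in type 1 diabetes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
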