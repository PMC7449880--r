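Package: brcadx
Title: Combined BRCA1/2 Sequence, Copy-Number and Methylation Diagnostics for Ovarian Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the combined assessment of BRCA1/2 deficiency in
    high-grade serous ovarian carcinoma: PARP-inhibitor eligibility rules over
    tiered somatic variant calls, read-depth copy-number calling on a 37-gene
    capture panel by concordance across four normalized coverage parameters,
    EPIC-style methylation beta-value quality control, BRCA1/2 promoter
    hypermethylation calling, and a genome-wide-methylation "BRCAness"
    classifier built from six base learners combined by a non-negative lasso
    stacking ensemble under leakage-free stratified fivefold cross-validation.
    Includes seeded synthetic-data generators for coverage, methylation and
    promoter cohorts with known truth, and packaged transcriptions of the
    reportable-variant and cross-validation-metric tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    MASS,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
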