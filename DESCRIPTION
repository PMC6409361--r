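Package: csfsig
Title: Blood-Based Prediction of CSF Amyloid-Beta Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and validating blood-based random-forest
    signatures of cerebrospinal-fluid amyloid-beta 1-42 status. Provides a
    synthetic cohort simulator with latent CSF levels, plasma analytes,
    amyloid PET records and conversion-to-dementia outcomes; missingness
    quality control with iterative random-forest imputation; random-forest
    regression and classification with permutation importance and partial
    dependence; nested cross-validation with data-driven ROC cutoff
    selection over six criteria; recursive feature elimination with a
    parsimony rule; and clinical validation via Kaplan-Meier, Cox and
    log-rank survival stratification and PET concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
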