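Package: immunoscreen
Title: Case-Control Analysis of Immune Population Frequency Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for systems-immunology case-control studies
    that start from a subjects-by-populations table of flow-cytometry
    percent-of-parent frequencies. Provides missingness filtering, Box-Cox
    normalisation with z-score standardisation, k-nearest-neighbour
    imputation, covariate-adjusted logistic and linear association screens,
    incremental L2-penalised logistic models with stratified cross-validated
    AUC curves, random-forest classifiers with out-of-bag depth tuning and
    Gini importance ranking, PCA-based immune-similarity embeddings,
    a constrained-permutation framework for spousal shared-environment
    concordance, and serology/severity-stratified nonparametric group
    comparisons. Includes a synthetic cohort generator with planted effects
    and exported ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
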