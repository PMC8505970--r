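Package: molPS
Title: Molecular Prognostic Score Modelling of Infliximab Response in
    Ulcerative Colitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a transcriptomic pipeline for predicting primary
    non-response to infliximab in ulcerative colitis from baseline mucosal
    expression profiles. Differentially expressed genes are screened with
    gene-wise Welch tests after batch correction, ranked by random-forest
    permutation importance (mean decrease in accuracy), binarized against
    cohort medians into a Gene Score table, and weighted by the maximum
    input-to-hidden weights of a shallow neural network trained with Adam on
    cross-entropy loss. The per-sample molecular prognostic score (mPS) is
    the weighted sum of Gene Scores, evaluated by tie-corrected ROC/AUC, with
    external-cohort validation and a synthetic cohort generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
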