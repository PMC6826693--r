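Package: exopipe
Title: Exosomal miRNA RT-qPCR Profiling, Chemoresistance Scoring and Survival Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal exosomal microRNA profiles
    measured by RT-qPCR array cards in high-risk neuroblastoma liquid biopsies.
    Implements threshold-cycle (CT) reliability filtering, global-mean delta-CT
    normalization, detection-rate filtering and worst-case imputation; principal
    variance component analysis (PVCA) for batch-effect assessment; paired
    delta-delta-CT differential expression with Benjamini-Hochberg correction;
    elastic-net selection of response signatures with leave-one-out
    cross-validation; a Laplace-smoothed per-patient, per-drug chemoresistance
    index; k-means patient stratification; and three-year event-free-survival
    log-rank analysis. A synthetic-cohort generator with planted ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    lme4,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
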