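Package: brcaness
Title: Lasso-Based Fusion of Serum miRNA and Clinical Metadata for BRCAness
    Classification and Cancer Risk Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-modality classifier of germline BRCA1/2 carrier
    status ("BRCAness") from a focused serum miRNA panel and binary clinical
    metadata. Each modality is reduced to a single scalar by an L1-penalized
    least-squares fit against the carrier label, the two-dimensional
    projection is classified by an antisymmetric two-class softmax, and the
    resulting BRCAness score in [0,1] is calibrated against binned 5-year
    relative cancer risk with a log-linear fit. Includes leakage-free nested
    ten-fold cross-validation with penalty selection, support-constrained
    (k-limited) model variants, ROC/Youden/confusion-matrix evaluation with
    DeLong confidence intervals, two-proportion Z-tests for cohort
    characteristics tables, and synthetic cohort generators emulating a
    biobank training population and a PLCO-style external validation cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
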