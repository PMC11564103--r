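Package: neurocostar
Title: Single-Cell Ex Vivo Drug-Response Scoring and Drug-Target
    Connectivity Signature Learning for Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for image-based ex vivo drug screening of
    glioblastoma patient samples and interpretable drug-target network
    modelling.  Implements pharmacoscopy (PCY) scoring of marker-gated
    cell populations with replicate statistics and hit calling, the
    layered drug -> extended-primary-target -> secondary-target
    connectivity network ("constellation") built from bioactivity and
    protein-protein-interaction tables, a cross-validated L1-penalized
    logistic regression learner of minimal connectivity signatures with
    in-silico compound screening (COSTAR), single-cell expressing-fraction
    specificity scores (neural and patient specificity), and calcium
    trace analysis (fold changes, dF/F0, peak detection and oscillation
    classification).  Ships synthetic-data generators with planted ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    mclust,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
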