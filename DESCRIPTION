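Package: statekinetics
Title: Cell-State Transition Kinetics from Single-Cell Transcriptomes and Motility Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the kinetics of cell-state transitions during stem cell
    activation from two complementary modalities. From spliced/unspliced
    single-cell UMI counts it estimates RNA velocity under the steady-state
    degradation model, maps principal-component embeddings to pseudotime with
    k-nearest-neighbor regression, simulates phase points through group-specific
    velocity fields, and calls lineage regression from the change-in-pseudotime
    distribution. From time-lapse motility tracks it extracts behavioral
    features, clusters behavior states, and measures state-transition
    magnitudes. Population-level statistics (rank-sum differential expression
    with fold-change and detection filters, gene-wise AUROC, difference-from-
    median overdispersion, classifier-based density-ratio Kullback-Leibler
    divergence, Wald tests for incorporation rates) and L1-sparse linear
    classification of cell age round out the toolkit. A synthetic-data module
    generates expression and track data with known kinetic ground truth from a
    transcription-splicing-degradation model and two-state motility switching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    readr,
    testthat (>= 3.0.0),
    withr,
    zoo
Config/testthat/edition: 3
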