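Package: harmonytm
Title: Scanner-Effect Unlearning for Traveling-Model Training of 3D
    Neuroimaging Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Adversarial scanner harmonization for the traveling-model
    approach to distributed learning on 3D brain volumes.  A lightweight
    fully convolutional 3D encoder with a binary disease head and a
    multiclass scanner head is trained sequentially, one center at a time;
    a per-batch three-step adversarial procedure (disease update, scanner
    head update on frozen features, confusion-loss encoder update) removes
    scanner-specific information from the learned representation while
    preserving disease signal.  Includes a seeded synthetic multi-center
    cohort generator with injectable scanner confounds, a centralized
    training baseline, task and scanner-leakage metrics, and a
    PCA-plus-linear-probe representation audit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    RcppArmadillo,
    Rcpp
Suggests:
    RNifti,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
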