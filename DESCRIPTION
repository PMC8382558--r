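Package: metabsae
Title: Sparse Stacked Autoencoders with Hessian-Free Fine-Tuning for
    Metabolomics Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of high-dimensional, small-sample metabolomic
    feature tables with a sparse stacked autoencoder: restricted Boltzmann
    machine weight initialization, greedy layer-wise pretraining with a
    KL-divergence sparsity penalty, a Softmax classification head, and
    fine-tuning by Hessian-free second-order optimization (Gauss-Newton
    curvature-vector products solved by conjugate gradients with
    Levenberg-Marquardt damping). Includes SMOTE augmentation, a
    leakage-safe stratified cross-validation harness with KNN and SVM
    baselines, Cohen's kappa, a shrinking-dataset ablation, a synthetic
    metabolomics data generator, and tidy/ggplot2 accessors for traces
    and reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
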