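Package: scLoras
Title: Synthetic Oversampling of Rare Cell Types in Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation of rare cell types in single-cell and single-nuclei
    RNA-sequencing count data via synthetic oversampling. Implements the
    Localized Random Affine Shadowsampling (LoRAS) algorithm, which rebalances
    an imbalanced binary cell-type classification problem by generating
    synthetic minority cells as random convex combinations of Gaussian-noise
    perturbed copies ("shadowsamples") of cells in small minority
    neighborhoods. Around the oversampler the package provides 10x-style count
    matrix input/output, log-normalization, marker gene ranking (Welch t, ROC
    AUC, ridge logistic scores), Gini-index plus DBSCAN unsupervised
    rare-cluster discovery as a baseline, stratified repeated cross-validation
    with fold-wise oversampling, k-nearest-neighbour and logistic-regression
    classifiers, transfer prediction onto unseen datasets, and a
    negative-binomial synthetic data generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    glmnet,
    Rtsne,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'utils.R'
    'io-counts.R'
    'loras.R'
    'markers.R'
    'rare-discovery.R'
    'annotate.R'
    'simulate.R'
    'zzz.R'
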