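#' scLoras: synthetic oversampling of rare cell types
#'
#' Rare cell populations (often fewer than 1 in 1000 cells) make supervised
#' annotation a severely imbalanced classification problem: classifiers
#' trained on the raw data rarely learn the minority class. scLoras
#' rebalances the training data with Localized Random Affine Shadowsampling
#' (LoRAS): around each rare cell it perturbs a small minority neighborhood
#' with Gaussian noise into "shadowsamples" and draws synthetic cells as
#' random convex combinations of them, then trains knn or logistic-regression
#' annotators under stratified cross-validation with fold-wise oversampling,
#' and applies the selected model to unseen datasets.
#'
#' Start with [simulateCounts()] for data, [rankMarkers()] for feature
#' selection, [lorasOversample()] for the oversampler itself,
#' [evaluateCV()] / [fitAnnotator()] / [predict()] for the supervised
#' pipeline and [giniDbscan()] for the unsupervised baseline.
#'
#' @keywords internal
"_PACKAGE"

#' @useDynLib scLoras, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom Rtsne Rtsne
#' @importFrom glmnet glmnet
#' @importFrom stats predict
NULL
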