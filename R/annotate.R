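#' Imbalance ratio of a binary-labeled dataset
#'
#' Number of majority-class cells divided by the number of minority (rare)
#' cells; e.g. 17 rare cells among 8635 give (8635 - 17) / 17 = 506.94.
#' Summaries report it to 2 decimals.
#'
#' @param y a [CellLabels-class], [LabeledDataset-class] or 0/1 vector.
#' @return the ratio (full precision).
#' @export
imbalanceRatio <- function(y) {
  y <- asLabelVector(y)
  nMin <- sum(y == 1L)
  nMaj <- sum(y == 0L)
  if (nMin == 0L || nMaj == 0L) stop("both classes must be non-empty")
  nMaj / nMin
}

asLabelVector <- function(y) {
  if (methods::is(y, "CellLabels") || methods::is(y, "LabeledDataset"))
    y <- y@label
  as.integer(y)
}

#' Stratified repeated cross-validation folds
#'
#' Per repeat the dataset is shuffled and each class is dealt round-robin
#' across the folds, so per-fold minority counts differ by at most 1 and
#' likewise for the majority: every fold keeps approximately the global
#' imbalance ratio. Repeat r uses seed \code{seed + r}, so fold assignments
#' are reproducible repeat by repeat.
#'
#' @param y binary labels (1 = minority).
#' @param nFolds folds per repeat; must not exceed the minority count.
#' @param nRepeats number of independent shuffles.
#' @param seed base seed.
#' @return list of length \code{nRepeats}; each element an integer vector of
#'   fold ids (1..nFolds) per sample.
#' @export
stratifiedFolds <- function(y, nFolds, nRepeats = 1L, seed = 1L) {
  y <- asLabelVector(y)
  n <- length(y)
  nMin <- sum(y == 1L)
  if (nMin == 0L || nMin == n) stop("both classes must be non-empty")
  if (nFolds > nMin)
    stop("nFolds (", nFolds, ") exceeds the ", nMin, " minority cells")
  lapply(seq_len(nRepeats), function(r) {
    withSeed(seed + r, {
      perm <- sample.int(n)
      assign <- integer(n)
      for (cls in c(1L, 0L)) {
        members <- perm[y[perm] == cls]
        assign[members] <- rep_len(seq_len(nFolds), length(members))
      }
      assign
    })
  })
}

#' Fit a classifier on a feature matrix
#'
#' The two classifiers of the pipeline: \code{"knn"}, a k-nearest-neighbour
#' majority vote over Euclidean distances whose rare-class probability is the
#' minority fraction among the \code{knnK} neighbors (default k = 30, large
#' enough that the vote rests on a statistically meaningful sample); and
#' \code{"logreg"}, L2-regularized logistic regression with pinned defaults
#' (ridge penalty equivalent to regularization strength C = 1, fitted
#' intercept, iteration cap) so "default settings" mean the same thing on
#' every system.
#'
#' @param x training feature matrix.
#' @param y binary labels (1 = minority).
#' @param cfg a [CVConfig-class] (supplies classifier and knnK).
#' @return an opaque fitted-model list consumed by [predictProb()].
#' @export
trainClassifier <- function(x, y, cfg) {
  x <- asDense(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training data has a single class")
  if (cfg@classifier == "knn") {
    if (cfg@knnK > nrow(x))
      stop("knnK (", cfg@knnK, ") exceeds the ", nrow(x), " training rows")
    list(type = "knn", train = x, y = y, k = cfg@knnK)
  } else {
    xx <- x
    if (ncol(xx) < 2L)
      xx <- cbind(xx, `.zero` = 0)  # glmnet needs >= 2 columns
    fit <- glmnet::glmnet(xx, factor(y, levels = c(0L, 1L)),
                          family = "binomial", alpha = 0,
                          lambda = 1 / nrow(xx), standardize = FALSE,
                          maxit = 1000L)
    list(type = "logreg", fit = fit, p = ncol(x), padded = ncol(x) < 2L)
  }
}

#' Rare-class probability of new rows under a fitted classifier
#'
#' knn: vote fraction of minority cells among the k nearest training rows
#' (ties in distance broken by smaller training-row index). logreg: the
#' fitted response probability.
#'
#' @param model a fit from [trainClassifier()].
#' @param newx matrix of rows to score.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predictProb <- function(model, newx) {
  newx <- asDense(newx)
  if (model$type == "knn") {
    .knnVoteCpp(model$train, model$y, newx, model$k)
  } else {
    xx <- newx
    if (model$padded) xx <- cbind(xx, 0)
    as.vector(stats::predict(model$fit, xx, type = "response"))
  }
}

#' Precision, recall and F1 for binary predictions
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN), F1 their harmonic
#' mean. Empty denominators yield 0 by convention (reported via a message),
#' so a classifier that never predicts the rare class scores (0, 0, 0) when
#' rare cells exist.
#'
#' @param yTrue,yPred 0/1 vectors of equal length.
#' @return named numeric vector (precision, recall, f1).
#' @export
classificationMetrics <- function(yTrue, yPred) {
  yTrue <- as.integer(yTrue)
  yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  tp <- sum(yTrue == 1L & yPred == 1L)
  fp <- sum(yTrue == 0L & yPred == 1L)
  fn <- sum(yTrue == 1L & yPred == 0L)
  precision <- if (tp + fp == 0L) {
    logMsg("no positive predictions; precision set to 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) {
    logMsg("no positive truths; recall set to 0")
    0
  } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Stratified repeated cross-validation with fold-wise oversampling
#'
#' For every repeat and fold: the held-out fold is set aside untouched, the
#' remaining folds form the training set, LoRAS oversampling (if enabled) is
#' applied to the training set only — synthetic cells can therefore never
#' leak into a test fold — a classifier is fitted and the held-out fold is
#' scored. Per-fold precision/recall/F1 are aggregated over all repeat x fold
#' cells.
#'
#' @param d a [LabeledDataset-class].
#' @param cv a [CVConfig-class].
#' @param loras a [LorasConfig-class] steering the oversampler, or
#'   \code{NULL} for defaults; ignored when \code{cv@oversample} is FALSE.
#'   When a training fold has too few minority cells for the configured
#'   neighborhood, \code{kNeighbors} is shrunk to (fold minority - 1) with a
#'   warning.
#' @return a [CVReport-class] (arm \code{"scsyno"} when oversampling,
#'   \code{"baseline"} otherwise).
#' @export
evaluateCV <- function(d, cv, loras = NULL) {
  stopifnot(methods::is(d, "LabeledDataset"), methods::is(cv, "CVConfig"))
  if (cv@oversample && is.null(loras)) loras <- lorasConfig(seed = cv@seed)
  x <- d@features
  y <- d@label
  assignments <- stratifiedFolds(y, cv@nFolds, cv@nRepeats, cv@seed)
  rows <- list()
  testIdx <- vector("list", cv@nRepeats)
  for (r in seq_len(cv@nRepeats)) {
    assign <- assignments[[r]]
    testIdx[[r]] <- vector("list", cv@nFolds)
    for (f in seq_len(cv@nFolds)) {
      test <- which(assign == f)
      train <- which(assign != f)
      testIdx[[r]][[f]] <- test
      xt <- x[train, , drop = FALSE]
      yt <- y[train]
      if (cv@oversample) {
        cfg <- loras
        nMinTrain <- sum(yt == 1L)
        if (cfg@kNeighbors >= nMinTrain) {
          logWarn("kNeighbors shrunk to %d for a training fold with %d minority cells",
                  nMinTrain - 1L, nMinTrain)
          cfg@kNeighbors <- nMinTrain - 1L
        }
        cfg@seed <- deriveSeed(cv@seed, (r - 1L) * cv@nFolds + f)
        over <- lorasOversample(xt, yt, cfg)
        xt <- over@features
        yt <- over@label
      }
      model <- trainClassifier(xt, yt, cv)
      prob <- predictProb(model, x[test, , drop = FALSE])
      met <- suppressMessages(
        classificationMetrics(y[test], as.integer(prob >= 0.5)))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, precision = met["precision"],
        recall = met["recall"], f1 = met["f1"], n_test = length(test),
        n_test_minority = sum(y[test] == 1L), row.names = NULL)
    }
  }
  methods::new("CVReport", folds = do.call(rbind, rows),
               arm = if (cv@oversample) "scsyno" else "baseline",
               testIndices = testIdx)
}

#' Summarize a CVReport
#'
#' @param report a [CVReport-class].
#' @return 3 x 2 matrix (precision/recall/f1 by mean/sd) over all repeat x
#'   fold cells.
#' @export
cvSummary <- function(report) {
  f <- report@folds
  out <- rbind(precision = c(mean(f$precision), stats::sd(f$precision)),
               recall = c(mean(f$recall), stats::sd(f$recall)),
               f1 = c(mean(f$f1), stats::sd(f$f1)))
  colnames(out) <- c("mean", "sd")
  out
}

#' Rank candidate models from their CV reports
#'
#' Candidates are ordered by mean F1, ties broken by mean recall then mean
#' precision — rare-cell detection favors recall, so among equally balanced
#' models the more sensitive one wins.
#'
#' @param reports list of [CVReport-class] objects.
#' @return integer permutation of \code{seq_along(reports)}, best first.
#' @export
rankModels <- function(reports) {
  s <- vapply(reports, function(r) cvSummary(r)[, "mean"], numeric(3))
  order(-s["f1", ], -s["recall", ], -s["precision", ])
}

#' Train the final annotator on the whole dataset
#'
#' Oversamples the full dataset (when enabled) and fits the selected
#' classifier, freezing the feature gene list, the normalization scale and
#' the decision threshold so the model can be applied verbatim to unseen
#' datasets.
#'
#' @param d a [LabeledDataset-class].
#' @param cv a [CVConfig-class] (classifier choice and oversampling switch).
#' @param loras optional [LorasConfig-class]; defaults applied when
#'   oversampling is enabled.
#' @param threshold decision threshold on the rare-class probability
#'   (default 0.5, the neutral choice after the classes are balanced).
#' @return a [TrainedAnnotator-class].
#' @export
fitAnnotator <- function(d, cv, loras = NULL, threshold = 0.5) {
  stopifnot(methods::is(d, "LabeledDataset"), methods::is(cv, "CVConfig"))
  x <- d@features
  y <- d@label
  usedLoras <- NULL
  if (cv@oversample) {
    if (is.null(loras)) loras <- lorasConfig(seed = cv@seed)
    nMin <- sum(y == 1L)
    if (loras@kNeighbors >= nMin) {
      logWarn("kNeighbors shrunk to %d for %d minority cells", nMin - 1L,
              nMin)
      loras@kNeighbors <- nMin - 1L
    }
    over <- lorasOversample(x, y, loras)
    x <- over@features
    y <- over@label
    usedLoras <- loras
  }
  model <- trainClassifier(x, y, cv)
  methods::new("TrainedAnnotator", model = model,
               classifier = cv@classifier, geneIds = colnames(d@features),
               normalized = d@normalized, lorasConfig = usedLoras,
               threshold = threshold)
}

#' Annotate cells of a (possibly unseen) dataset
#'
#' Builds the feature matrix the annotator expects — exactly its stored gene
#' list, in stored order, with absent genes handled per policy — and returns
#' the rare-class probability and thresholded label per cell, preserving cell
#' order.
#'
#' @param object a [TrainedAnnotator-class].
#' @param newdata a [CountMatrix-class] on the same normalization scale the
#'   model was trained on, or a plain feature matrix with gene columns.
#' @param missingGenes policy for stored genes absent from \code{newdata}.
#' @param ... ignored.
#' @return data.frame with columns cell_id, probability, label.
#' @export
setMethod("predict", "TrainedAnnotator",
          function(object, newdata, missingGenes = c("zero_fill", "error"),
                   ...) {
  missingGenes <- match.arg(missingGenes)
  if (methods::is(newdata, "CountMatrix")) {
    if (newdata@normalized != object@normalized)
      stop("normalization scale of newdata (",
           if (newdata@normalized) "normalized" else "raw",
           ") does not match the model (",
           if (object@normalized) "normalized" else "raw", ")")
    mat <- newdata@counts
  } else {
    mat <- newdata
  }
  mat <- asDense(mat)
  genes <- object@geneIds
  present <- genes %in% colnames(mat)
  if (!any(present)) stop("all model genes are missing from newdata")
  if (!all(present)) {
    if (missingGenes == "error")
      stop("missing genes: ", paste(genes[!present], collapse = ", "))
    logWarn("%d model gene(s) absent from newdata; zero-filled",
            sum(!present))
  }
  feat <- matrix(0, nrow = nrow(mat), ncol = length(genes),
                 dimnames = list(rownames(mat), genes))
  feat[, genes[present]] <- mat[, genes[present], drop = FALSE]
  prob <- predictProb(object@model, feat)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("cell_", seq_len(nrow(mat)))
  data.frame(cell_id = ids, probability = prob,
             label = as.integer(prob >= object@threshold))
})

#' Save / load a trained annotator
#'
#' Serializes the annotator (gene list, parameters and fitted model) to a
#' single file; a reloaded annotator yields identical predictions.
#'
#' @param a a [TrainedAnnotator-class].
#' @param path archive path.
#' @return \code{saveAnnotator}: the path, invisibly; \code{loadAnnotator}:
#'   the [TrainedAnnotator-class].
#' @export
saveAnnotator <- function(a, path) {
  stopifnot(methods::is(a, "TrainedAnnotator"))
  saveRDS(a, path)
  invisible(path)
}

#' @rdname saveAnnotator
#' @export
loadAnnotator <- function(path) {
  a <- readRDS(path)
  if (!methods::is(a, "TrainedAnnotator"))
    stop("file does not contain a TrainedAnnotator")
  a
}

#' Write a CVReport to disk
#'
#' @param report a [CVReport-class].
#' @param path output path; \code{.json} writes per-fold metrics plus the
#'   summary as JSON, anything else the per-fold table as TSV.
#' @return the path, invisibly.
#' @export
writeCVReport <- function(report, path) {
  if (grepl("\\.json$", path)) {
    s <- cvSummary(report)
    jsonlite::write_json(
      list(arm = report@arm, folds = report@folds,
           summary = list(
             precision = list(mean = s["precision", "mean"],
                              sd = s["precision", "sd"]),
             recall = list(mean = s["recall", "mean"],
                           sd = s["recall", "sd"]),
             f1 = list(mean = s["f1", "mean"], sd = s["f1", "sd"]))),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(cbind(arm = report@arm, report@folds), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write per-cell predictions as TSV (cell id, probability, label)
#'
#' @param predictions data.frame from [predict()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePredictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
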