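test_that("imbalance ratio is majority over minority", {
  expect_equal(round(imbalanceRatio(c(rep(0, 8618), rep(1, 17))), 2),
               506.94)
  expect_equal(imbalanceRatio(rep(c(0, 1), each = 10)), 1)
  expect_equal(imbalanceRatio(c(rep(0, 99), 1)), 99)
  expect_error(imbalanceRatio(rep(1, 5)), "non-empty")
  lab <- cellLabels(paste0("c", 1:4), c(1, 0, 0, 0))
  expect_equal(imbalanceRatio(lab), 3)
})

test_that("stratified folds balance both classes to within one cell", {
  y <- c(rep(1L, 30), rep(0L, 270))
  f <- stratifiedFolds(y, 3, nRepeats = 2, seed = 5)
  for (r in 1:2) {
    expect_equal(as.integer(table(f[[r]][y == 1L])), rep(10L, 3))
    majCounts <- table(f[[r]][y == 0L])
    expect_lte(max(majCounts) - min(majCounts), 1)
  }
  expect_false(identical(f[[1]], f[[2]]))

  # 17 minority over 3 folds: counts {6, 6, 5}
  y2 <- c(rep(1L, 17), rep(0L, 8618))
  f2 <- stratifiedFolds(y2, 3, seed = 1)[[1]]
  expect_equal(sort(as.integer(table(f2[y2 == 1L])), decreasing = TRUE),
               c(6L, 6L, 5L))

  expect_identical(stratifiedFolds(y, 3, 2, seed = 5), f)
  expect_error(stratifiedFolds(y, 31, seed = 1), "exceeds")
})

test_that("metrics follow the precision/recall/F1 conventions", {
  expect_equal(unname(classificationMetrics(c(1, 0, 1), c(1, 0, 1))),
               c(1, 1, 1))
  yTrue <- c(rep(1, 4), rep(0, 6))       # TP=3, FN=1, FP=3
  yPred <- c(1, 1, 1, 0, 1, 1, 1, 0, 0, 0)
  expect_equal(unname(classificationMetrics(yTrue, yPred)),
               c(0.5, 0.75, 0.6))
  expect_message(
    m <- classificationMetrics(c(1, 1, 0), c(0, 0, 0)), "precision")
  expect_equal(unname(m), c(0, 0, 0))
  set.seed(1)
  a <- rbinom(50, 1, 0.3); b <- rbinom(50, 1, 0.4)
  met <- suppressMessages(classificationMetrics(a, b))
  if (met["precision"] + met["recall"] > 0)
    expect_equal(met[["f1"]],
                 2 * met[["precision"]] * met[["recall"]] /
                   (met[["precision"]] + met[["recall"]]))
})

test_that("knn classifier equals the brute-force neighbor vote", {
  set.seed(2)
  train <- matrix(rnorm(500 * 4), ncol = 4)
  y <- rbinom(500, 1, 0.2)
  test <- matrix(rnorm(40 * 4), ncol = 4)
  model <- trainClassifier(train, y, cvConfig(classifier = "knn",
                                              knnK = 11))
  expect_equal(predictProb(model, test), bruteKnnProb(train, y, test, 11),
               tolerance = 1e-12)
  # k = all rows on balanced data: global vote of 0.5 everywhere
  bal <- trainClassifier(train[1:100, ], rep(c(1L, 0L), 50),
                         cvConfig(classifier = "knn", knnK = 100))
  expect_equal(predictProb(bal, test), rep(0.5, 40))
  expect_error(trainClassifier(train, y, cvConfig(knnK = 501)), "exceeds")
  expect_error(trainClassifier(train, rep(1L, 500), cvConfig()),
               "single class")
})

test_that("both classifiers separate a linearly separable toy", {
  d <- separableDataset()
  for (clf in c("knn", "logreg")) {
    cfg <- cvConfig(classifier = clf, knnK = 5, oversample = FALSE)
    model <- trainClassifier(features(d), labelVector(d), cfg)
    pred <- as.integer(predictProb(model, features(d)) >= 0.5)
    met <- classificationMetrics(labelVector(d), pred)
    expect_equal(met[["recall"]], 1)
  }
})

test_that("cross-validation keeps test folds pure and stratified", {
  d <- selectTop(easySim(seed = 3, nCells = 1200), 10)
  cv <- cvConfig(nFolds = 4, nRepeats = 2, seed = 6, oversample = TRUE)
  rep1 <- evaluateCV(d, cv, lorasConfig(kNeighbors = 5, seed = 6))
  n <- nrow(features(d))
  nMin <- sum(labelVector(d) == 1L)
  for (r in 1:2) {
    test <- rep1@testIndices[[r]]
    all <- sort(unlist(test))
    # test folds partition the original rows: no synthetic index possible
    expect_equal(all, seq_len(n))
    minPerFold <- vapply(test, function(i) sum(labelVector(d)[i] == 1L),
                         integer(1))
    expect_lte(max(minPerFold) - min(minPerFold), 1L)
  }
  # baseline on the same seed sees the very same folds
  rep0 <- evaluateCV(d, cvConfig(nFolds = 4, nRepeats = 2, seed = 6,
                                 oversample = FALSE))
  expect_identical(rep0@testIndices, rep1@testIndices)
  expect_equal(rep1@arm, "scsyno")
  expect_equal(rep0@arm, "baseline")
  expect_true(all(cvFolds(rep1)$f1 >= 0 & cvFolds(rep1)$f1 <= 1))
})

test_that("both arms are perfect on a perfectly separated simulation", {
  d <- separableDataset(nMin = 25, nMaj = 100, gap = 30)
  for (ov in c(TRUE, FALSE)) {
    r <- evaluateCV(d, cvConfig(nFolds = 5, nRepeats = 1, seed = 2,
                                classifier = "knn", knnK = 5,
                                oversample = ov),
                    lorasConfig(kNeighbors = 3, seed = 2))
    expect_equal(cvSummary(r)["f1", "mean"], 1)
  }
})

test_that("oversampling improves recall on an overlapping simulation", {
  d <- selectTop(simulateCounts(simConfig("hard", seed = 51)), 20)
  cvA <- cvConfig(nFolds = 5, nRepeats = 1, seed = 51, oversample = TRUE)
  cvB <- cvConfig(nFolds = 5, nRepeats = 1, seed = 51, oversample = FALSE)
  recallA <- cvSummary(evaluateCV(d, cvA))["recall", "mean"]
  recallB <- cvSummary(evaluateCV(d, cvB))["recall", "mean"]
  expect_gt(recallA, recallB)
})

test_that("model ranking favors F1 then recall then precision", {
  mk <- function(p, r) {
    f1 <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
    new("CVReport",
        folds = data.frame(repeat_ = 1L, fold = 1L, precision = p,
                           recall = r, f1 = f1, n_test = 10L,
                           n_test_minority = 2L),
        arm = "baseline", testIndices = list())
  }
  reports <- list(mk(0.5, 0.5), mk(0.9, 0.9), mk(0.945, 0.855))
  # report 2: F1 0.9; report 3: F1 0.8977...; report 1: F1 0.5
  expect_equal(rankModels(reports), c(2L, 3L, 1L))
  # equal F1, higher recall wins
  reports2 <- list(mk(0.8, 0.6), mk(0.6, 0.8))
  expect_equal(rankModels(reports2)[1], 2L)
})

test_that("a trained annotator transfers, serializes and stays deterministic", {
  sim <- easySim(seed = 4, nCells = 1500)
  d <- selectTop(sim, 15)
  cv <- cvConfig(oversample = TRUE, seed = 4, knnK = 15)
  ann <- fitAnnotator(d, cv, lorasConfig(kNeighbors = 5, seed = 4))
  ann2 <- fitAnnotator(d, cv, lorasConfig(kNeighbors = 5, seed = 4))
  norm <- logNormalize(sim$matrix)
  pred <- predict(ann, norm)
  expect_identical(pred, predict(ann2, norm))
  expect_equal(pred$cell_id, cellIds(norm))
  expect_true(all(pred$label %in% 0:1))

  # save / load round trip yields identical predictions
  p <- withr::local_tempfile(fileext = ".rds")
  saveAnnotator(ann, p)
  expect_identical(predict(loadAnnotator(p), norm), pred)

  # scale mismatch and missing genes
  expect_error(predict(ann, sim$matrix), "normalization")
  sub <- countMatrix(asDenseMat(counts(norm))[, 1:150], normalized = TRUE,
                     sparsify = FALSE)
  missing <- sum(!geneIds(ann) %in% geneIds(sub))
  if (missing > 0) expect_warning(predict(ann, sub), "zero-filled")
  none <- countMatrix(matrix(1.5, 3, 2,
                             dimnames = list(paste0("c", 1:3),
                                             c("zz1", "zz2"))),
                      normalized = TRUE, sparsify = FALSE)
  expect_error(predict(ann, none), "missing")

  # all-zero cells score identically
  zeros <- matrix(0, 4, length(geneIds(ann)),
                  dimnames = list(paste0("z", 1:4), geneIds(ann)))
  pz <- predict(ann, countMatrix(zeros, normalized = TRUE,
                                 sparsify = FALSE))
  expect_equal(length(unique(pz$probability)), 1L)
})

test_that("CV reports write as JSON and TSV", {
  d <- separableDataset(nMin = 20, nMaj = 60)
  r <- evaluateCV(d, cvConfig(nFolds = 2, nRepeats = 1, seed = 1,
                              classifier = "logreg", oversample = FALSE))
  pj <- withr::local_tempfile(fileext = ".json")
  writeCVReport(r, pj)
  back <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(back$arm, "baseline")
  expect_equal(back$summary$f1$mean, cvSummary(r)["f1", "mean"])
  pt <- withr::local_tempfile(fileext = ".tsv")
  writeCVReport(r, pt)
  expect_equal(nrow(read.table(pt, header = TRUE)), 2L)
})
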