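test_that("knnNeighborhood finds Euclidean neighbors with index tie-break", {
  pts <- cbind(c(0, 1, 2, 10))
  expect_equal(knnNeighborhood(pts, 1, 2), c(2L, 3L))
  expect_equal(sort(knnNeighborhood(pts, 2, 3)), c(1L, 3L, 4L))
  expect_error(knnNeighborhood(pts, 1, 4), "smaller")

  # duplicated points: ties resolved toward smaller row indices
  dup <- matrix(1, nrow = 5, ncol = 2)
  expect_equal(knnNeighborhood(dup, 4, 2), c(1L, 2L))
  expect_equal(knnNeighborhood(dup, 1, 2), c(2L, 3L))
})

test_that("shadowsamples reduce to source points at zero noise and clip at 0", {
  pts <- rbind(c(1, 2), c(3, 4), c(0, 0.5))
  set.seed(1)
  sh <- makeShadowsamples(pts, sigma = 0, nShadow = 3)
  expect_equal(nrow(sh@samples), 9L)
  expect_equal(sh@samples, pts[rep(1:3, each = 3), ])

  set.seed(2)
  sh2 <- makeShadowsamples(matrix(0, 1, 4), sigma = 5, nShadow = 100)
  expect_true(all(sh2@samples >= 0))
  expect_true(any(sh2@samples == 0))  # clipping visibly engaged
  expect_error(makeShadowsamples(pts, sigma = c(1, 1, 1), nShadow = 2),
               "per feature")
})

test_that("shadowsample noise is centered on the source point (CLT bound)", {
  point <- matrix(c(5, 2, 7), nrow = 1)
  set.seed(11)
  sh <- makeShadowsamples(point, sigma = 0.01, nShadow = 1e4)
  # sample mean of 1e4 N(x, 0.01) draws lies within 3 * 0.01/100 of x
  expect_true(all(abs(colMeans(sh@samples) - point[1, ]) <= 3 * 1e-4))
})

test_that("convex combinations stay in the per-feature envelope", {
  set.seed(3)
  pool <- matrix(runif(50), nrow = 10)
  for (i in 1:20) {
    s <- convexCombine(pool, nAff = 4)
    expect_true(all(s >= apply(pool, 2, min) - 1e-12))
    expect_true(all(s <= apply(pool, 2, max) + 1e-12))
  }
  # nAff = 1 returns a shadowsample verbatim
  set.seed(4)
  s1 <- convexCombine(pool, nAff = 1)
  expect_true(any(apply(pool, 1, function(r) isTRUE(all.equal(r, s1)))))
  # identical shadowsamples collapse to that point for any weights
  same <- matrix(2, nrow = 6, ncol = 3)
  expect_equal(unname(convexCombine(same, nAff = 5)), rep(2, 3))
  expect_error(convexCombine(pool, nAff = 11), "exceeds")
})

test_that("zero-noise synthetic samples lie in their neighborhood hull", {
  set.seed(8)
  nMin <- 10
  xMin <- matrix(runif(nMin * 4, 0, 5), nrow = nMin)
  x <- rbind(xMin, matrix(runif(30 * 4, 10, 20), nrow = 30))
  y <- c(rep(1L, nMin), rep(0L, 30))
  cfg <- lorasConfig(kNeighbors = 4, sigma = 0, nGen = 5, nAff = 5,
                     nShadow = 1, embedding = "raw", seed = 21)
  o <- lorasOversample(x, y, cfg)
  synth <- features(o)[provenance(o) == "synthetic", ]
  parent <- rep(seq_len(nMin), each = 5)
  for (r in seq_len(nrow(synth))) {
    i <- parent[r]
    nbrs <- knnNeighborhood(xMin, i, 4)
    V <- xMin[c(i, nbrs), ]
    expect_lt(hullDistance(synth[r, ], V), 1e-6)
  }
})

test_that("auto generation balances classes exactly (17 vs 8618)", {
  set.seed(12)
  x <- rbind(matrix(rnorm(17 * 5, mean = 10), nrow = 17),
             matrix(rnorm(8618 * 5), nrow = 8618))
  x[x < 0] <- 0
  y <- c(rep(1L, 17), rep(0L, 8618))
  o <- lorasOversample(x, y, lorasConfig(kNeighbors = 3, seed = 5))
  expect_equal(sum(labelVector(o) == 1L), 8618L)
  expect_equal(sum(labelVector(o) == 1L), sum(labelVector(o) == 0L))
  expect_equal(sum(provenance(o) == "synthetic"), 8601L)
  # original rows are present, unchanged, and first
  expect_equal(features(o)[seq_len(8635), ], x, ignore_attr = TRUE)
})

test_that("oversampling is bit-deterministic under a fixed seed", {
  set.seed(30)
  x <- matrix(runif(200), nrow = 40)
  y <- c(rep(1L, 8), rep(0L, 32))
  cfg <- lorasConfig(kNeighbors = 3, seed = 77)
  o1 <- lorasOversample(x, y, cfg)
  o2 <- lorasOversample(x, y, cfg)
  expect_identical(o1@features, o2@features)
  expect_identical(o1@label, o2@label)
  o3 <- lorasOversample(x, y, lorasConfig(kNeighbors = 3, seed = 78))
  expect_false(identical(o1@features, o3@features))
})

test_that("degenerate inputs behave per contract", {
  x <- matrix(runif(20), nrow = 10)
  expect_error(lorasOversample(x, rep(1L, 10), lorasConfig(kNeighbors = 2)),
               "non-empty")
  expect_error(lorasOversample(x, c(rep(1L, 3), rep(0L, 7)),
                               lorasConfig(kNeighbors = 3)),
               "smaller")
  # two coincident minority points, sigma = 0, k = 1: all synthetics equal it
  x2 <- rbind(c(2, 2), c(2, 2), matrix(8, 10, 2))
  y2 <- c(1L, 1L, rep(0L, 10))
  o <- lorasOversample(x2, y2, lorasConfig(kNeighbors = 1, sigma = 0,
                                           seed = 2))
  synth <- features(o)[provenance(o) == "synthetic", , drop = FALSE]
  expect_equal(unname(synth), matrix(2, nrow(synth), 2), tolerance = 1e-12)
})

test_that("synthetic samples stay local to their parent neighborhood", {
  set.seed(41)
  nMin <- 25
  xMin <- matrix(rnorm(nMin * 6, mean = 5, sd = 0.5), nrow = nMin)
  x <- rbind(xMin, matrix(rnorm(100 * 6), nrow = 100))
  x[x < 0] <- 0
  y <- c(rep(1L, nMin), rep(0L, 100))
  sigma <- 0.05
  cfg <- lorasConfig(kNeighbors = 5, sigma = sigma, nGen = 4,
                     embedding = "raw", seed = 13)
  o <- lorasOversample(x, y, cfg)
  synth <- features(o)[provenance(o) == "synthetic", ]
  parent <- rep(seq_len(nMin), each = 4)
  for (i in seq_len(nMin)) {
    nbrs <- knnNeighborhood(xMin, i, 5)
    maxNbrDist <- max(sqrt(rowSums((xMin[nbrs, , drop = FALSE] -
                                      rep(xMin[i, ], each = 5))^2)))
    rows <- which(parent == i)
    d <- sqrt(rowSums((synth[rows, , drop = FALSE] -
                         rep(xMin[i, ], each = length(rows)))^2))
    expect_lte(mean(d), maxNbrDist + 3 * sigma * sqrt(6))
  }
})

test_that("minority embedding engages only above the size guard", {
  set.seed(6)
  small <- matrix(rnorm(17 * 10), nrow = 17)
  cfg <- lorasConfig(tsneMinPoints = 50, seed = 1)
  expect_null(embedMinority(small, cfg))  # 17 glial-like cells: raw space
  expect_null(embedMinority(small, lorasConfig(embedding = "raw", seed = 1)))
  expect_error(embedMinority(small[1, , drop = FALSE], cfg), "2 minority")

  # two tight clusters of 100: embedded 5-NNs stay within their cluster
  x <- rbind(matrix(rnorm(100 * 8, 0, 0.3), ncol = 8),
             matrix(rnorm(100 * 8, 6, 0.3), ncol = 8))
  memb <- rep(1:2, each = 100)
  emb <- embedMinority(x, lorasConfig(tsneMinPoints = 50, seed = 9))
  expect_equal(dim(emb), c(200L, 2L))
  agree <- vapply(seq_len(200), function(i) {
    nb <- knnNeighborhood(emb, i, 5)
    mean(memb[nb] == memb[i])
  }, numeric(1))
  expect_gte(mean(agree), 0.9)
  # same config, same seed: identical embedding
  emb2 <- embedMinority(x, lorasConfig(tsneMinPoints = 50, seed = 9))
  expect_identical(emb, emb2)
})

test_that("LoRAS config serializes through JSON", {
  cfg <- lorasConfig(kNeighbors = 7, sigma = c(0.1, 0.2), nAff = 12,
                     nGen = 3, embedding = "raw", seed = 99)
  p <- withr::local_tempfile(fileext = ".json")
  writeLorasConfig(cfg, p)
  back <- readLorasConfig(p)
  expect_equal(back@kNeighbors, 7L)
  expect_equal(back@sigma, c(0.1, 0.2))
  expect_equal(back@nAff, 12L)
  expect_equal(back@nGen, 3L)
  expect_equal(back@embedding, "raw")
  # auto fields survive the round trip as auto
  auto <- lorasConfig(seed = 1)
  writeLorasConfig(auto, p)
  back2 <- readLorasConfig(p)
  expect_true(is.na(back2@nAff))
  expect_length(back2@sigma, 0)
})

test_that("config validity catches inconsistent parameters", {
  expect_error(lorasConfig(kNeighbors = 0), "kNeighbors")
  expect_error(lorasConfig(sigma = -1), "sigma")
  expect_error(lorasConfig(nAff = 20, nShadow = 2, kNeighbors = 3),
               "pool")
  expect_error(lorasConfig(embedding = "umap"), "embedding")
})
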