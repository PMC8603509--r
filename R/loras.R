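#' Embed the minority class in two dimensions
#'
#' Computes the 2-D t-SNE embedding in which oversampling neighborhoods are
#' found, with perplexity \code{min(30, (n - 1) / 3)} and a fixed seed. A
#' meaningful embedding needs enough minority cells: below
#' \code{cfg@tsneMinPoints} (or with \code{embedding = "raw"}) the function
#' returns \code{NULL}, the pass-through marker meaning neighborhoods are
#' computed in raw feature space.
#'
#' @param xMin minority-class feature matrix (cells x genes, >= 2 rows).
#' @param cfg a [LorasConfig-class].
#' @return a 2-column coordinate matrix, or \code{NULL} for raw-space
#'   fallback.
#' @export
embedMinority <- function(xMin, cfg) {
  xMin <- asDense(xMin)
  n <- nrow(xMin)
  if (n < 2L) stop("need at least 2 minority points")
  if (cfg@embedding == "raw" || n < cfg@tsneMinPoints) return(NULL)
  perplexity <- min(30, (n - 1) / 3)
  withSeed(cfg@seed, {
    fit <- Rtsne::Rtsne(xMin, dims = 2, perplexity = perplexity,
                        check_duplicates = FALSE,
                        pca = ncol(xMin) > 50, verbose = FALSE)
    fit$Y
  })
}

#' k-nearest neighbors of one row
#'
#' Euclidean nearest rows to row \code{index}, excluding the row itself, with
#' ties broken deterministically by smaller row index.
#'
#' @param coords numeric matrix.
#' @param index row whose neighborhood is sought.
#' @param k number of neighbors, \code{k < nrow(coords)}.
#' @return integer vector of k row indices, nearest first.
#' @export
knnNeighborhood <- function(coords, index, k) {
  coords <- asDense(coords)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of rows")
  if (index < 1L || index > n) stop("index out of range")
  d2 <- colSums((t(coords) - coords[index, ])^2)
  d2[index] <- Inf
  order(d2, seq_len(n))[seq_len(k)]
}

#' Generate shadowsamples for one oversampling neighborhood
#'
#' Each of the neighborhood's cells (the minority point p itself plus its k
#' nearest minority neighbors) is copied \code{nShadow} times and perturbed by
#' independent per-feature Gaussian noise; the perturbed copies are the
#' shadowsamples. Values are clipped at 0 from below, since expression cannot
#' be negative. Draws come from the current RNG stream; seed upstream for
#' reproducibility.
#'
#' @param points neighborhood matrix (rows: p and its neighbors).
#' @param sigma per-feature noise standard deviations (length 1 recycled, or
#'   one per feature).
#' @param nShadow copies per neighborhood member.
#' @param parentPoint index of p within the minority class (bookkeeping).
#' @return a [ShadowSet-class] with \code{nrow(points) * nShadow} samples.
#' @export
makeShadowsamples <- function(points, sigma, nShadow, parentPoint = 1L) {
  points <- asDense(points)
  p <- ncol(points)
  if (length(sigma) == 1L) sigma <- rep(sigma, p)
  if (length(sigma) != p)
    stop("sigma must have one entry per feature")
  if (any(sigma < 0)) stop("sigma entries must be >= 0")
  idx <- rep(seq_len(nrow(points)), each = nShadow)
  n <- length(idx)
  noise <- matrix(stats::rnorm(n * p), nrow = n) *
    matrix(sigma, nrow = n, ncol = p, byrow = TRUE)
  samples <- points[idx, , drop = FALSE] + noise
  samples[samples < 0] <- 0
  methods::new("ShadowSet", samples = samples,
               parentPoint = as.integer(parentPoint))
}

#' Draw one synthetic sample as a random convex combination
#'
#' Picks \code{nAff} distinct shadowsamples uniformly without replacement and
#' combines them with flat-Dirichlet weights (non-negative, summing to 1): a
#' random weighted average of perturbed minority cells. Draws come from the
#' current RNG stream.
#'
#' @param shadow a [ShadowSet-class] (or plain matrix of shadowsamples).
#' @param nAff number of shadowsamples per combination.
#' @return numeric vector, one synthetic sample.
#' @export
convexCombine <- function(shadow, nAff) {
  samples <- if (methods::is(shadow, "ShadowSet")) shadow@samples else
    asDense(shadow)
  n <- nrow(samples)
  if (nAff > n)
    stop("nAff (", nAff, ") exceeds the ", n, " available shadowsamples")
  sel <- sample.int(n, nAff)
  w <- as.vector(rdirichlet1(1L, nAff))
  drop(crossprod(samples[sel, , drop = FALSE], w))
}

# Resolve auto fields of a LorasConfig against the data at hand.
resolveLorasConfig <- function(cfg, xMin) {
  m <- nrow(xMin)
  p <- ncol(xMin)
  nAff <- cfg@nAff
  if (is.na(nAff)) nAff <- if (m < 50L) 50L else min(p, 100L)
  nShadow <- cfg@nShadow
  if (is.na(nShadow))
    nShadow <- as.integer(ceiling(nAff / (cfg@kNeighbors + 1L)) + 1L)
  if (nAff > nShadow * (cfg@kNeighbors + 1L))
    stop("nAff exceeds the shadowsample pool nShadow * (kNeighbors + 1)")
  sigma <- cfg@sigma
  if (length(sigma) == 0L) {
    sigma <- 0.005 * apply(xMin, 2, stats::sd)
    sigma[!is.finite(sigma)] <- 0
    sigma <- pmax(sigma, 1e-6)
  } else if (length(sigma) == 1L) {
    sigma <- rep(sigma, p)
  } else if (length(sigma) != p) {
    stop("sigma must have one entry per feature")
  }
  list(nAff = as.integer(nAff), nShadow = as.integer(nShadow), sigma = sigma)
}

#' LoRAS synthetic oversampling of the minority class
#'
#' End-to-end Localized Random Affine Shadowsampling. For each minority cell
#' p: find its \code{kNeighbors} nearest minority cells (in a 2-D t-SNE
#' embedding of the minority class when it is large enough, otherwise in raw
#' feature space), perturb the neighborhood with per-feature Gaussian noise
#' into a pool of shadowsamples, and draw synthetic cells as random convex
#' combinations of \code{nAff} shadowsamples. With \code{nGen} auto the
#' per-point generation counts are chosen so the classes balance exactly:
#' each minority point contributes \code{floor((n_maj - n_min) / n_min)}
#' synthetic cells and the first \code{(n_maj - n_min) mod n_min} points one
#' extra. The whole procedure is deterministic given \code{cfg@seed}.
#'
#' @param x a [LabeledDataset-class], or a cells x genes feature matrix.
#' @param y binary labels (1 = minority); ignored when \code{x} is a
#'   [LabeledDataset-class].
#' @param cfg a [LorasConfig-class].
#' @return an [OversampledDataset-class]: original rows unchanged and first,
#'   synthetic minority rows appended with provenance \code{"synthetic"}.
#' @export
lorasOversample <- function(x, y = NULL, cfg = lorasConfig()) {
  if (methods::is(x, "LabeledDataset")) {
    y <- x@label
    x <- x@features
  }
  x <- asDense(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("label length must match rows")
  nMin <- sum(y == 1L)
  nMaj <- sum(y == 0L)
  if (nMin == 0L || nMaj == 0L) stop("both classes must be non-empty")
  if (cfg@kNeighbors >= nMin)
    stop("kNeighbors (", cfg@kNeighbors, ") must be smaller than the ",
         nMin, " minority points")
  minIdx <- which(y == 1L)
  xMin <- x[minIdx, , drop = FALSE]
  res <- resolveLorasConfig(cfg, xMin)
  k <- cfg@kNeighbors

  # per-point generation counts
  if (is.na(cfg@nGen)) {
    deficit <- max(0L, nMaj - nMin)
    gen <- rep(deficit %/% nMin, nMin)
    if (deficit %% nMin > 0L)
      gen[seq_len(deficit %% nMin)] <- gen[seq_len(deficit %% nMin)] + 1L
  } else {
    gen <- rep(cfg@nGen, nMin)
  }
  total <- sum(gen)

  synth <- withSeed(cfg@seed, {
    space <- embedMinority(xMin, cfg)
    if (is.null(space)) space <- xMin
    d2 <- pairwiseSq(space, space)
    diag(d2) <- Inf
    out <- matrix(0, nrow = total, ncol = ncol(x))
    row <- 0L
    for (i in seq_len(nMin)) {
      if (gen[i] == 0L) next
      nbrs <- order(d2[i, ], seq_len(nMin))[seq_len(k)]
      pool <- makeShadowsamples(xMin[c(i, nbrs), , drop = FALSE],
                                res$sigma, res$nShadow, parentPoint = i)
      for (g in seq_len(gen[i])) {
        row <- row + 1L
        out[row, ] <- convexCombine(pool, res$nAff)
      }
    }
    out
  })

  feats <- rbind(x, synth)
  rn <- rownames(x)
  if (is.null(rn)) rn <- paste0("cell_", seq_len(nrow(x)))
  rownames(feats) <- c(rn, sprintf("synthetic_%d", seq_len(total)))
  colnames(feats) <- colnames(x)
  methods::new("OversampledDataset",
               features = feats,
               label = c(y, rep(1L, total)),
               provenance = c(rep("original", nrow(x)),
                              rep("synthetic", total)))
}

#' Write an oversampled dataset as TSV
#'
#' One row per cell (original and synthetic) with the label and a provenance
#' column.
#'
#' @param o an [OversampledDataset-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeOversampled <- function(o, path) {
  df <- data.frame(id = rownames(o@features), o@features,
                   label = o@label, provenance = o@provenance,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a LorasConfig as JSON
#'
#' @param cfg a [LorasConfig-class].
#' @param path JSON file path.
#' @return \code{writeLorasConfig}: the path, invisibly;
#'   \code{readLorasConfig}: a [LorasConfig-class].
#' @export
writeLorasConfig <- function(cfg, path) {
  x <- list(kNeighbors = cfg@kNeighbors, nShadow = cfg@nShadow,
            sigma = cfg@sigma, nAff = cfg@nAff, nGen = cfg@nGen,
            embedding = cfg@embedding, tsneMinPoints = cfg@tsneMinPoints,
            seed = cfg@seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeLorasConfig
#' @export
readLorasConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asOpt <- function(v) if (is.null(v) || !length(v) || is.na(v[1])) NA else v
  sigma <- unlist(x$sigma)
  lorasConfig(kNeighbors = x$kNeighbors,
              nShadow = asOpt(x$nShadow),
              sigma = if (length(sigma)) sigma else numeric(0),
              nAff = asOpt(x$nAff),
              nGen = asOpt(x$nGen),
              embedding = x$embedding, tsneMinPoints = x$tsneMinPoints,
              seed = x$seed)
}
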