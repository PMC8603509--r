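#' Rank genes as rare-type markers
#'
#' Scores every gene for how well it discriminates the minority (rare) cells
#' from the rest, by one of three methods:
#' \describe{
#'   \item{ttest}{absolute Welch (unequal-variance) t statistic, minority vs
#'     rest — robust to the extreme group-size asymmetry of rare types.}
#'   \item{roc}{folded AUC \code{max(AUC, 1 - AUC)} of the gene's expression
#'     as a score for the minority label, so down-regulated markers also rank
#'     high.}
#'   \item{logreg}{absolute slope of a one-gene ridge logistic regression on
#'     standardized expression.}
#' }
#' Genes with zero variance score 0 under every method. The ranking is sorted
#' by decreasing score with ties broken by gene id.
#'
#' @param d a [LabeledDataset-class] with at least 2 cells per class.
#' @param method scoring method.
#' @return a [MarkerRanking-class].
#' @export
rankMarkers <- function(d, method = c("ttest", "roc", "logreg")) {
  method <- match.arg(method)
  stopifnot(methods::is(d, "LabeledDataset"))
  x <- d@features
  y <- d@label
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L) stop("each class needs at least 2 cells")
  vtot <- apply(x, 2, stats::var)
  scores <- switch(method,
    ttest = welchT(x, y),
    roc = foldedAuc(x, y),
    logreg = logregScores(x, y))
  scores[vtot == 0] <- 0
  ord <- order(-scores, colnames(x))
  methods::new("MarkerRanking", geneIds = colnames(x)[ord],
               scores = scores[ord], method = method)
}

welchT <- function(x, y) {
  a <- x[y == 1L, , drop = FALSE]
  b <- x[y == 0L, , drop = FALSE]
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  se2 <- va / nrow(a) + vb / nrow(b)
  t <- abs(ma - mb) / sqrt(se2)
  # groups internally constant: a perfect separator if the means differ
  t[se2 == 0 & abs(ma - mb) > 0] <- Inf
  t[se2 == 0 & abs(ma - mb) == 0] <- 0
  t
}

# AUC per gene via the rank-sum identity (ties handled by midranks).
foldedAuc <- function(x, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  auc <- apply(x, 2, function(g) {
    r <- rank(g)
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  pmax(auc, 1 - auc)
}

logregScores <- function(x, y) {
  n <- nrow(x)
  apply(x, 2, function(g) {
    s <- stats::sd(g)
    if (s == 0) return(0)
    z <- (g - mean(g)) / s
    abs(ridgeLogistic1d(z, y, lambda = 1 / n))
  })
}

# One-feature ridge logistic regression (penalty on the slope only),
# Newton/IRLS, bounded by the ridge so perfect separation cannot diverge.
ridgeLogistic1d <- function(z, y, lambda = 1e-3, maxit = 50L, tol = 1e-10) {
  beta <- c(0, 0)  # intercept, slope
  X <- cbind(1, z)
  n <- length(y)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    grad <- crossprod(X, y - p) - c(0, n * lambda * beta[2])
    H <- crossprod(X * w, X) + diag(c(1e-12, n * lambda))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta[2]
}

#' Take the top n genes of a ranking
#'
#' @param r a [MarkerRanking-class].
#' @param n number of genes, \code{n <= length(geneIds(r))}.
#' @return character vector of the n best gene ids, best first.
#' @export
topMarkers <- function(r, n) {
  stopifnot(methods::is(r, "MarkerRanking"))
  if (n > length(r@geneIds))
    stop("n (", n, ") exceeds the ", length(r@geneIds), " ranked genes")
  if (n < 1L) stop("n must be >= 1")
  r@geneIds[seq_len(n)]
}

#' Gini index of an expression vector
#'
#' Inequality of a gene's expression across cells:
#' \deqn{G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar x}}
#' 0 for perfectly even expression, approaching 1 when expression concentrates
#' in very few cells — the signature of a rare-population marker. An all-zero
#' vector returns 0 by convention. Computed via the sorted-value identity,
#' equivalent to the pairwise-difference sum.
#'
#' @param x non-negative numeric vector, length >= 2.
#' @return Gini coefficient in [0, 1).
#' @export
giniIndex <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values")
  if (any(x < 0)) stop("negative entries")
  s <- sum(x)
  if (s == 0) return(0)
  n <- length(x)
  xs <- sort(x)
  2 * sum(seq_len(n) * xs) / (n * s) - (n + 1) / n
}

#' Min-max normalize a vector of Gini indices
#'
#' Maps to [0, 1] by \code{(g - min) / (max - min)}; a constant vector maps to
#' all zeros (including the single-element case).
#'
#' @param g numeric vector, length >= 1.
#' @return numeric vector in [0, 1].
#' @export
normalizeGini <- function(g) {
  if (!length(g)) stop("empty vector")
  r <- max(g) - min(g)
  if (r == 0) return(rep(0, length(g)))
  (g - min(g)) / r
}

#' Write a marker ranking as two-column TSV (gene, score)
#'
#' @param r a [MarkerRanking-class].
#' @param path output path. The gene column is readable back with
#'   [readMarkerList()] via \code{cut -f1}-style use, or pass \code{scores =
#'   FALSE} to write the plain one-gene-per-line list.
#' @param scores include the score column (default TRUE).
#' @return the path, invisibly.
#' @export
writeRanking <- function(r, path, scores = TRUE) {
  if (scores) {
    utils::write.table(data.frame(gene = r@geneIds, score = r@scores),
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  } else {
    writeLines(r@geneIds, path)
  }
  invisible(path)
}
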