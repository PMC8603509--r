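# Independent reference implementations used as oracles. Deliberately naive
# (loops, O(n^2)); they must not share code paths with the package.

# Gini coefficient by the literal double sum over all pairs.
bruteGini <- function(x) {
  n <- length(x)
  if (mean(x) == 0) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# knn minority vote fraction, one test row at a time, distances by explicit
# subtraction, ties by smaller training-row index.
bruteKnnProb <- function(train, y, test, k) {
  vapply(seq_len(nrow(test)), function(i) {
    d2 <- vapply(seq_len(nrow(train)),
                 function(j) sum((train[j, ] - test[i, ])^2), numeric(1))
    nb <- order(d2, seq_along(d2))[seq_len(k)]
    mean(y[nb])
  }, numeric(1))
}

# DBSCAN reference: core points by pairwise counting, core clusters by
# union-find over core pairs within eps, components numbered by smallest core
# row index, border points joined to the cluster of their smallest-index core
# neighbor.
bruteDbscan <- function(x, eps, minSize) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  within <- d <= eps
  core <- rowSums(within) >= minSize
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in which(core)) for (j in which(core)) {
    if (i < j && within[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  labels <- rep(-1L, n)
  roots <- unique(vapply(which(core), find, integer(1)))
  roots <- sort(roots)  # smallest core row index first
  for (ci in seq_along(roots)) {
    members <- which(core)[vapply(which(core), find, integer(1)) ==
                             roots[ci]]
    labels[members] <- ci - 1L
  }
  for (i in which(!core)) {
    cn <- which(within[i, ] & core)
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  labels
}

# Convex-hull membership of a point x in the hull of the rows of V, solved
# exactly for small vertex sets: enumerate every non-empty subset S of
# vertices, solve the equality-constrained least squares (weights summing to
# 1 on S) via its KKT system, keep solutions with non-negative weights, and
# return the smallest achieved distance. Exact for the <= 5-point
# neighborhoods it is used on.
hullDistance <- function(x, V) {
  m <- nrow(V)
  best <- Inf
  for (bits in seq_len(2^m - 1)) {
    S <- which(bitwAnd(bits, 2^(seq_len(m) - 1)) > 0)
    Vs <- V[S, , drop = FALSE]
    G <- Vs %*% t(Vs)
    b <- as.vector(Vs %*% x)
    k <- length(S)
    kkt <- rbind(cbind(2 * G, rep(1, k)), c(rep(1, k), 0))
    sol <- tryCatch(solve(kkt, c(2 * b, 1)), error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol[seq_len(k)]
    if (any(w < -1e-9)) next
    d <- sqrt(sum((as.vector(t(Vs) %*% w) - x)^2))
    best <- min(best, d)
  }
  best
}

# AUC by literal pair counting (ties count half).
brutePairAuc <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
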