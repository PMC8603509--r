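# Internal helpers shared across modules.

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards,
# so seeded operations are deterministic without clobbering the global stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and stream index, kept within the
# 32-bit integer range.
deriveSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009 + stream) %% 2147483647)
}

# Squared Euclidean distances between the rows of a and the rows of b,
# as an nrow(a) x nrow(b) matrix. Clipped at 0 against cancellation error.
pairwiseSq <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Flat Dirichlet draw: n vectors of length k with concentration 1.
rdirichlet1 <- function(n, k) {
  g <- matrix(stats::rexp(n * k), nrow = n)
  g / rowSums(g)
}

# Warn through a consistent channel; messages go to stderr.
logWarn <- function(...) warning(sprintf(...), call. = FALSE)
logMsg <- function(...) message(sprintf(...))

asDense <- function(m) {
  if (is.matrix(m)) m else as.matrix(m)
}
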