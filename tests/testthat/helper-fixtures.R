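# Small in-code fixtures shared across test files.

asDenseMat <- function(m) as.matrix(m)

# 3-gene x 2-cell triplet directory with entries (g1,c1)=5, (g2,c2)=1.
writeTinyTriplet <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "2 2 1"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  dir
}

# A linearly separable 2-D labeled dataset.
separableDataset <- function(nMin = 20, nMaj = 80, gap = 10, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(nMaj * 2), ncol = 2),
             matrix(rnorm(nMin * 2, mean = gap), ncol = 2))
  colnames(x) <- c("gA", "gB")
  rownames(x) <- paste0("c", seq_len(nrow(x)))
  labeledDataset(x, c(rep(0L, nMaj), rep(1L, nMin)), normalized = TRUE)
}

# Standard small simulation used by several pipeline tests.
easySim <- function(seed = 1, ...) {
  simulateCounts(simConfig("easy", seed = seed, ...))
}

# Full supervised pipeline on a simulation: rank markers, keep top n, return
# the restricted LabeledDataset.
selectTop <- function(sim, n = 20, method = "ttest") {
  norm <- logNormalize(sim$matrix)
  d <- alignAndSubset(norm, sim$labels, geneIds(norm))
  alignAndSubset(norm, sim$labels, topMarkers(rankMarkers(d, method), n))
}
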