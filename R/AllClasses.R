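#' @import methods
#' @importFrom Matrix Matrix rowSums colSums t readMM writeMM
NULL

#' Cell-by-gene count matrix
#'
#' Container for a single-cell expression matrix with cells as rows and genes
#' as columns. This orientation is the single in-memory convention of the
#' package: all readers transpose on ingest if the on-disk layout is
#' genes-by-cells (the 10x convention). The matrix holds raw counts
#' (\code{normalized = FALSE}, all entries integral) or log-normalized
#' expression (\code{normalized = TRUE}).
#'
#' @slot counts cells x genes matrix, base \code{matrix} or sparse
#'   \code{Matrix::dgCMatrix}, with cell ids as rownames and gene ids as
#'   colnames.
#' @slot normalized logical flag; \code{FALSE} means raw integer counts.
#'
#' @seealso [countMatrix()], [readMtxTriplet()], [logNormalize()]
#' @export
setClass("CountMatrix",
  representation(counts = "ANY", normalized = "logical"))

setValidity("CountMatrix", function(object) {
  m <- object@counts
  if (!(is.matrix(m) || is(m, "Matrix")))
    return("counts must be a base matrix or a Matrix object")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must carry cell ids (rownames) and gene ids (colnames)")
  if (anyDuplicated(rownames(m))) return("duplicate cell ids")
  if (anyDuplicated(colnames(m))) return("duplicate gene ids")
  vals <- if (is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(vals) && any(!is.finite(vals))) return("non-finite entries")
  if (length(vals) && any(vals < 0)) return("negative entries")
  if (isFALSE(object@normalized) && length(vals) &&
      any(abs(vals - round(vals)) > 1e-8))
    return("raw counts must be integers")
  if (length(object@normalized) != 1L) return("normalized must be length 1")
  TRUE
})

#' Construct a CountMatrix
#'
#' @param counts cells x genes numeric matrix (dense or sparse).
#' @param cellIds,geneIds identifiers; taken from \code{dimnames(counts)} when
#'   omitted.
#' @param normalized logical; \code{FALSE} for raw counts.
#' @param sparsify store as sparse \code{dgCMatrix} when the matrix density is
#'   below 0.5 (default \code{TRUE}).
#' @return a [CountMatrix-class] object.
#' @export
countMatrix <- function(counts, cellIds = rownames(counts),
                        geneIds = colnames(counts), normalized = FALSE,
                        sparsify = TRUE) {
  if (is.null(cellIds) || is.null(geneIds))
    stop("cellIds and geneIds are required")
  dimnames(counts) <- list(as.character(cellIds), as.character(geneIds))
  if (sparsify && !is(counts, "sparseMatrix")) {
    dens <- sum(counts != 0) / max(1, length(counts))
    if (dens < 0.5) counts <- Matrix(counts, sparse = TRUE)
  }
  new("CountMatrix", counts = counts, normalized = normalized)
}

#' Binary rare-type labels per cell
#'
#' One label per cell: 1 marks the expert-annotated rare (minority) cell type,
#' 0 everything else.
#'
#' @slot cellIds character vector of unique cell identifiers.
#' @slot label integer vector of 0/1, parallel to \code{cellIds}.
#' @export
setClass("CellLabels",
  representation(cellIds = "character", label = "integer"))

setValidity("CellLabels", function(object) {
  if (length(object@cellIds) != length(object@label))
    return("cellIds and label lengths differ")
  if (anyDuplicated(object@cellIds)) return("duplicate cell ids")
  if (length(object@label) && !all(object@label %in% c(0L, 1L)))
    return("labels must be 0/1")
  TRUE
})

#' @rdname CellLabels-class
#' @param cellIds,label see slots.
#' @export
cellLabels <- function(cellIds, label) {
  new("CellLabels", cellIds = as.character(cellIds),
      label = as.integer(label))
}

#' Feature matrix plus binary labels, ready for training
#'
#' A dense cells x selected-genes expression matrix aligned with a 0/1 rare
#' type label per cell, as produced by [alignAndSubset()].
#'
#' @slot features dense cells x genes matrix (cell ids as rownames, gene ids
#'   as colnames).
#' @slot label integer 0/1 per row.
#' @slot normalized logical, whether \code{features} is on the log-normalized
#'   scale.
#' @export
setClass("LabeledDataset",
  representation(features = "matrix", label = "integer",
                 normalized = "logical"))

setValidity("LabeledDataset", function(object) {
  if (nrow(object@features) != length(object@label))
    return("label length must equal number of rows")
  if (length(object@label) && !all(object@label %in% c(0L, 1L)))
    return("labels must be 0/1")
  TRUE
})

#' @rdname LabeledDataset-class
#' @param features,label,normalized see slots.
#' @export
labeledDataset <- function(features, label, normalized = TRUE) {
  new("LabeledDataset", features = as.matrix(features),
      label = as.integer(label), normalized = normalized)
}

#' LoRAS generation parameters
#'
#' All parameters steering synthetic sample generation. Fields left at their
#' \code{NA}/empty defaults are resolved from the data at oversampling time
#' (see [lorasOversample()] for the resolution rules).
#'
#' @slot kNeighbors size of the oversampling neighborhood: number of nearest
#'   minority neighbors of each minority point (the point itself is added, so
#'   a neighborhood holds \code{kNeighbors + 1} cells).
#' @slot nShadow shadowsample copies drawn per neighborhood member;
#'   \code{NA} = auto (\code{ceiling(nAff / (kNeighbors + 1)) + 1}).
#' @slot sigma per-feature Gaussian noise standard deviations used to create
#'   shadowsamples; length 0 = auto (0.005 x per-feature minority sd, floored
#'   at 1e-6).
#' @slot nAff shadowsamples combined into one synthetic sample (the affine
#'   combination size); \code{NA} = auto (50 when the minority has fewer than
#'   50 cells, else \code{min(n_features, 100)}).
#' @slot nGen synthetic samples generated per minority point; \code{NA} =
#'   auto, which balances the classes exactly.
#' @slot embedding \code{"tsne"} to compute minority neighborhoods in a 2-D
#'   t-SNE embedding of the minority class, \code{"raw"} to use the feature
#'   space directly.
#' @slot tsneMinPoints minimum minority size before the t-SNE embedding is
#'   engaged; below it neighborhoods fall back to raw feature space.
#' @slot seed integer seed making generation fully deterministic.
#' @export
setClass("LorasConfig",
  representation(kNeighbors = "integer", nShadow = "integer",
                 sigma = "numeric", nAff = "integer", nGen = "integer",
                 embedding = "character", tsneMinPoints = "integer",
                 seed = "integer"))

setValidity("LorasConfig", function(object) {
  if (object@kNeighbors < 1L) return("kNeighbors must be >= 1")
  if (!is.na(object@nShadow) && object@nShadow < 1L)
    return("nShadow must be >= 1")
  if (length(object@sigma) && any(object@sigma < 0))
    return("sigma entries must be >= 0")
  if (!is.na(object@nAff) && object@nAff < 1L) return("nAff must be >= 1")
  if (!is.na(object@nGen) && object@nGen < 1L) return("nGen must be >= 1")
  if (!object@embedding %in% c("tsne", "raw"))
    return("embedding must be 'tsne' or 'raw'")
  if (!is.na(object@nAff) && !is.na(object@nShadow) &&
      object@nAff > object@nShadow * (object@kNeighbors + 1L))
    return("nAff exceeds the shadowsample pool nShadow * (kNeighbors + 1)")
  if (object@tsneMinPoints < 3L) return("tsneMinPoints must be >= 3")
  TRUE
})

#' @rdname LorasConfig-class
#' @param kNeighbors,nShadow,sigma,nAff,nGen,embedding,tsneMinPoints,seed see
#'   slots; \code{nGen = "auto"} (or \code{NA}) balances the classes exactly.
#' @export
lorasConfig <- function(kNeighbors = 30L, nShadow = NA, sigma = numeric(0),
                        nAff = NA, nGen = "auto", embedding = "tsne",
                        tsneMinPoints = 50L, seed = 1L) {
  if (identical(nGen, "auto")) nGen <- NA
  new("LorasConfig",
      kNeighbors = as.integer(kNeighbors), nShadow = as.integer(nShadow),
      sigma = as.numeric(sigma), nAff = as.integer(nAff),
      nGen = as.integer(nGen), embedding = embedding,
      tsneMinPoints = as.integer(tsneMinPoints), seed = as.integer(seed))
}

#' Shadowsample pool for one minority neighborhood
#'
#' Gaussian-noise perturbed copies of the cells in the oversampling
#' neighborhood of one minority point p (p itself plus its k nearest minority
#' neighbors). With all noise standard deviations zero each shadowsample
#' equals its source cell exactly.
#'
#' @slot samples matrix of (kNeighbors + 1) * nShadow rows x genes.
#' @slot parentPoint index (within the minority class) of the point whose
#'   neighborhood generated the pool.
#' @export
setClass("ShadowSet",
  representation(samples = "matrix", parentPoint = "integer"))

#' Rebalanced dataset with provenance
#'
#' Output of [lorasOversample()]: the original rows unchanged, followed by
#' synthetic minority rows, with a per-row provenance flag.
#'
#' @slot features numeric matrix (original rows first, then synthetic).
#' @slot label integer 0/1 per row; synthetic rows always carry 1.
#' @slot provenance character, \code{"original"} or \code{"synthetic"} per row.
#' @export
setClass("OversampledDataset",
  representation(features = "matrix", label = "integer",
                 provenance = "character"))

setValidity("OversampledDataset", function(object) {
  n <- nrow(object@features)
  if (length(object@label) != n || length(object@provenance) != n)
    return("label/provenance lengths must match rows")
  if (!all(object@provenance %in% c("original", "synthetic")))
    return("provenance must be original/synthetic")
  if (any(object@label[object@provenance == "synthetic"] != 1L))
    return("synthetic rows must carry the minority label")
  TRUE
})

#' Marker gene ranking
#'
#' Genes ordered by decreasing discriminative score for the rare type, ties
#' broken by gene id.
#'
#' @slot geneIds ordered character vector.
#' @slot scores numeric per gene, decreasing.
#' @slot method one of \code{"ttest"}, \code{"roc"}, \code{"logreg"}.
#' @export
setClass("MarkerRanking",
  representation(geneIds = "character", scores = "numeric",
                 method = "character"))

setValidity("MarkerRanking", function(object) {
  if (length(object@geneIds) != length(object@scores))
    return("geneIds and scores lengths differ")
  if (is.unsorted(rev(object@scores), na.rm = TRUE))
    return("scores must be sorted decreasing")
  TRUE
})

#' Density-based clustering result
#'
#' DBSCAN output: one integer label per cell, \code{-1} for noise and
#' \code{0..C-1} for clusters, each cluster holding at least \code{minSize}
#' members.
#'
#' @slot cellIds character per row of the clustered matrix.
#' @slot labels integer per cell.
#' @slot eps neighborhood radius used.
#' @slot minSize minimum cluster size used (the point itself counts).
#' @export
setClass("DensityClustering",
  representation(cellIds = "character", labels = "integer", eps = "numeric",
                 minSize = "integer"))

setValidity("DensityClustering", function(object) {
  if (length(object@cellIds) != length(object@labels))
    return("cellIds and labels lengths differ")
  if (length(object@labels) && any(object@labels < -1L))
    return("labels must be >= -1")
  TRUE
})

#' Cross-validation configuration
#'
#' @slot nFolds folds per repeat (stratified; every fold receives at least
#'   one minority cell).
#' @slot nRepeats independent shuffles of the dataset.
#' @slot seed base seed; repeat r uses \code{seed + r}.
#' @slot classifier \code{"knn"} or \code{"logreg"}.
#' @slot knnK neighbors for the knn vote (default 30).
#' @slot oversample logical: apply LoRAS to the training folds.
#' @export
setClass("CVConfig",
  representation(nFolds = "integer", nRepeats = "integer", seed = "integer",
                 classifier = "character", knnK = "integer",
                 oversample = "logical"))

setValidity("CVConfig", function(object) {
  if (object@nFolds < 2L) return("nFolds must be >= 2")
  if (object@nRepeats < 1L) return("nRepeats must be >= 1")
  if (!object@classifier %in% c("knn", "logreg"))
    return("classifier must be 'knn' or 'logreg'")
  if (object@knnK < 1L) return("knnK must be >= 1")
  TRUE
})

#' @rdname CVConfig-class
#' @param nFolds,nRepeats,seed,classifier,knnK,oversample see slots.
#' @export
cvConfig <- function(nFolds = 5L, nRepeats = 5L, seed = 1L,
                     classifier = c("knn", "logreg"), knnK = 30L,
                     oversample = TRUE) {
  classifier <- match.arg(classifier)
  new("CVConfig", nFolds = as.integer(nFolds),
      nRepeats = as.integer(nRepeats), seed = as.integer(seed),
      classifier = classifier, knnK = as.integer(knnK),
      oversample = isTRUE(oversample))
}

#' Cross-validation report
#'
#' Per-fold precision/recall/F1 for every repeat, plus the test-fold row
#' indices so fold hygiene (no synthetic row in any test fold, stratification)
#' can be audited after the fact.
#'
#' @slot folds data.frame with columns repeat_, fold, precision, recall, f1,
#'   n_test, n_test_minority.
#' @slot arm \code{"baseline"} (no oversampling) or \code{"scsyno"}.
#' @slot testIndices list (one per repeat) of lists of integer test-row
#'   indices into the original dataset.
#' @export
setClass("CVReport",
  representation(folds = "data.frame", arm = "character",
                 testIndices = "list"))

setValidity("CVReport", function(object) {
  f <- object@folds
  need <- c("repeat_", "fold", "precision", "recall", "f1")
  if (!all(need %in% names(f))) return("missing fold columns")
  m <- unlist(f[, c("precision", "recall", "f1")])
  if (length(m) && (any(m < 0) || any(m > 1)))
    return("metrics must lie in [0, 1]")
  TRUE
})

#' Trained rare-cell annotator
#'
#' A fitted classifier frozen together with everything needed to apply it to
#' an unseen dataset: the ordered gene list it consumes, the normalization
#' scale it expects, the oversampling configuration used (if any) and the
#' decision threshold.
#'
#' @slot model internal fit object (knn neighbor store or glmnet fit).
#' @slot classifier \code{"knn"} or \code{"logreg"}.
#' @slot geneIds ordered feature gene list; prediction consumes exactly this
#'   list in this order.
#' @slot normalized whether the model was trained on log-normalized values.
#' @slot lorasConfig the [LorasConfig-class] used for training, or \code{NULL}.
#' @slot threshold decision threshold on the rare-class probability.
#' @export
setClass("TrainedAnnotator",
  representation(model = "list", classifier = "character",
                 geneIds = "character", normalized = "logical",
                 lorasConfig = "ANY", threshold = "numeric"))

setValidity("TrainedAnnotator", function(object) {
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must be in (0, 1)")
  if (!object@classifier %in% c("knn", "logreg"))
    return("classifier must be 'knn' or 'logreg'")
  TRUE
})

#' Synthetic dataset configuration
#'
#' Parameters of the negative-binomial single-cell count simulator: a majority
#' background plus one rare cluster distinguished by up-regulated marker
#' genes. Presets bundle the regimes the pipeline is designed around:
#' \code{"easy"} (well-separated ultra-rare cluster, marker fold change 8),
#' \code{"hard"} (transient overlapping cluster: fold change 2 and doubled
#' overdispersion), \code{"transfer"} (same generative parameters as
#' \code{"easy"}, intended to be drawn under a new seed to emulate an unseen
#' dataset of the same biology).
#'
#' @slot nCells,nGenes matrix dimensions.
#' @slot imbalanceRatio majority:minority ratio (> 1); the minority count is
#'   \code{round(nCells / (1 + imbalanceRatio))}.
#' @slot nMarkers number of true marker genes.
#' @slot markerFoldChange mean fold elevation of markers in minority cells.
#' @slot baselineMeanLogMu,baselineMeanLogSd lognormal parameters of baseline
#'   gene means.
#' @slot dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @slot librarySizeSd sdlog of the per-cell lognormal library scaling.
#' @slot separation preset name.
#' @slot seed integer seed for the cell-level draw (labels, library sizes,
#'   counts).
#' @slot biologySeed integer seed for the gene-level draw (baseline means,
#'   marker gene positions); \code{NA} means reuse \code{seed}. Two configs
#'   sharing a biologySeed describe the same biology sampled as different
#'   datasets — the transfer scenario.
#' @export
setClass("SimConfig",
  representation(nCells = "integer", nGenes = "integer",
                 imbalanceRatio = "numeric", nMarkers = "integer",
                 markerFoldChange = "numeric", baselineMeanLogMu = "numeric",
                 baselineMeanLogSd = "numeric", dispersion = "numeric",
                 librarySizeSd = "numeric", separation = "character",
                 seed = "integer", biologySeed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@imbalanceRatio <= 1) return("imbalanceRatio must be > 1")
  if (object@nMarkers > object@nGenes) return("nMarkers exceeds nGenes")
  if (object@markerFoldChange < 1) return("markerFoldChange must be >= 1")
  if (object@dispersion <= 0) return("dispersion must be > 0")
  if (object@librarySizeSd < 0) return("librarySizeSd must be >= 0")
  if (round(object@nCells / (1 + object@imbalanceRatio)) < 2)
    return("configuration yields fewer than 2 minority cells")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "CountMatrix", function(object) {
  m <- object@counts
  cat(sprintf("CountMatrix: %d cells x %d genes (%s, %s)\n",
              nrow(m), ncol(m),
              if (is(m, "sparseMatrix")) "sparse" else "dense",
              if (object@normalized) "log-normalized" else "raw counts"))
})

setMethod("show", "CellLabels", function(object) {
  cat(sprintf("CellLabels: %d cells, %d minority (rare), %d majority\n",
              length(object@label), sum(object@label == 1L),
              sum(object@label == 0L)))
})

setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf(
    "LabeledDataset: %d cells x %d genes, %d minority, imbalance %.2f\n",
    nrow(object@features), ncol(object@features), sum(object@label == 1L),
    if (sum(object@label == 1L) > 0)
      sum(object@label == 0L) / sum(object@label == 1L) else NA_real_))
})

setMethod("show", "LorasConfig", function(object) {
  fmt <- function(x) if (length(x) == 0) "auto" else
    if (is.na(x[1])) "auto" else paste(signif(x[1], 4))
  cat(sprintf(
    "LorasConfig: k=%d, nShadow=%s, nAff=%s, nGen=%s, sigma=%s, %s, seed=%d\n",
    object@kNeighbors, fmt(object@nShadow), fmt(object@nAff),
    fmt(object@nGen),
    if (length(object@sigma)) "fixed" else "auto", object@embedding,
    object@seed))
})

setMethod("show", "OversampledDataset", function(object) {
  cat(sprintf(
    "OversampledDataset: %d rows (%d original, %d synthetic), %d minority\n",
    nrow(object@features), sum(object@provenance == "original"),
    sum(object@provenance == "synthetic"), sum(object@label == 1L)))
})

setMethod("show", "MarkerRanking", function(object) {
  cat(sprintf("MarkerRanking (%s): %d genes; top: %s\n", object@method,
              length(object@geneIds),
              paste(utils::head(object@geneIds, 5), collapse = ", ")))
})

setMethod("show", "DensityClustering", function(object) {
  k <- length(unique(object@labels[object@labels >= 0L]))
  cat(sprintf(
    "DensityClustering: %d cells, %d clusters, %d noise (eps=%g, minSize=%d)\n",
    length(object@labels), k, sum(object@labels == -1L), object@eps,
    object@minSize))
})

setMethod("show", "CVReport", function(object) {
  s <- cvSummary(object)
  cat(sprintf(
    "CVReport [%s]: %d folds; precision %.3f+-%.3f recall %.3f+-%.3f f1 %.3f+-%.3f\n",
    object@arm, nrow(object@folds), s["precision", "mean"],
    s["precision", "sd"], s["recall", "mean"], s["recall", "sd"],
    s["f1", "mean"], s["f1", "sd"]))
})

setMethod("show", "TrainedAnnotator", function(object) {
  cat(sprintf(
    "TrainedAnnotator: %s on %d genes (%s scale), threshold %.2f, %s\n",
    object@classifier, length(object@geneIds),
    if (object@normalized) "log-normalized" else "raw",
    object@threshold,
    if (is.null(object@lorasConfig)) "baseline (no oversampling)"
    else "LoRAS-oversampled"))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig [%s]: %d cells x %d genes, IR %.1f, %d markers (fold %.1f), seed %d\n",
    object@separation, object@nCells, object@nGenes, object@imbalanceRatio,
    object@nMarkers, object@markerFoldChange, object@seed))
})

# ---- accessors --------------------------------------------------------------

#' Accessors for package containers
#'
#' @param object a package S4 object.
#' @return \code{counts()} the cells x genes matrix; \code{cellIds()} /
#'   \code{geneIds()} identifier vectors; \code{isNormalized()} the scale
#'   flag; \code{labelVector()} the integer 0/1 labels; \code{provenance()}
#'   per-row origin flags; \code{clusterLabels()} DBSCAN labels;
#'   \code{cvFolds()} the per-fold metric table.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "CountMatrix", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setMethod("cellIds", "CountMatrix", function(object) rownames(object@counts))
#' @rdname accessors
#' @export
setMethod("cellIds", "CellLabels", function(object) object@cellIds)
#' @rdname accessors
#' @export
setMethod("cellIds", "LabeledDataset",
          function(object) rownames(object@features))
#' @rdname accessors
#' @export
setMethod("cellIds", "DensityClustering", function(object) object@cellIds)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "CountMatrix", function(object) colnames(object@counts))
#' @rdname accessors
#' @export
setMethod("geneIds", "LabeledDataset",
          function(object) colnames(object@features))
#' @rdname accessors
#' @export
setMethod("geneIds", "MarkerRanking", function(object) object@geneIds)
#' @rdname accessors
#' @export
setMethod("geneIds", "TrainedAnnotator", function(object) object@geneIds)

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setMethod("isNormalized", "CountMatrix", function(object) object@normalized)
#' @rdname accessors
#' @export
setMethod("isNormalized", "LabeledDataset",
          function(object) object@normalized)

#' @rdname accessors
#' @export
setGeneric("labelVector", function(object) standardGeneric("labelVector"))
#' @rdname accessors
#' @export
setMethod("labelVector", "CellLabels", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("labelVector", "LabeledDataset", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("labelVector", "OversampledDataset", function(object) object@label)

#' @rdname accessors
#' @export
setGeneric("features", function(object) standardGeneric("features"))
#' @rdname accessors
#' @export
setMethod("features", "LabeledDataset", function(object) object@features)
#' @rdname accessors
#' @export
setMethod("features", "OversampledDataset", function(object) object@features)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "OversampledDataset",
          function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "DensityClustering",
          function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("markerScores", function(object) standardGeneric("markerScores"))
#' @rdname accessors
#' @export
setMethod("markerScores", "MarkerRanking", function(object) {
  stats::setNames(object@scores, object@geneIds)
})

#' @rdname accessors
#' @export
setGeneric("cvFolds", function(object) standardGeneric("cvFolds"))
#' @rdname accessors
#' @export
setMethod("cvFolds", "CVReport", function(object) object@folds)
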