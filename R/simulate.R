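#' Build a synthetic-data configuration
#'
#' Presets bundle the three regimes the pipeline must handle:
#' \describe{
#'   \item{easy}{a well-separated ultra-rare cluster (marker fold change 8),
#'     the glial-like case where even a baseline classifier does well.}
#'   \item{hard}{a transient, overlapping cluster: fold change 2 and doubled
#'     overdispersion (negative-binomial size halved), the
#'     proliferative-cardiomyocyte-like case where a baseline classifier
#'     misses rare cells and oversampling should recover recall.}
#'   \item{transfer}{identical generative parameters to \code{easy}; draw it
#'     under a different seed to emulate an unseen dataset of the same
#'     biology for transfer prediction.}
#' }
#'
#' @param preset one of \code{"easy"}, \code{"hard"}, \code{"transfer"}.
#' @param nCells,nGenes matrix dimensions.
#' @param imbalanceRatio majority:minority ratio (> 1).
#' @param nMarkers number of true marker genes.
#' @param markerFoldChange marker mean elevation in minority cells;
#'   \code{NULL} = preset value (easy/transfer 8, hard 2).
#' @param baselineMeanLogMu,baselineMeanLogSd lognormal parameters of
#'   baseline gene means.
#' @param dispersion negative-binomial size; \code{NULL} = preset value
#'   (easy/transfer 2, hard 1).
#' @param librarySizeSd sdlog of per-cell lognormal library scaling.
#' @param seed integer seed for the cell-level draw.
#' @param biologySeed integer seed for the gene-level draw (baseline means
#'   and marker positions); \code{NA} (default) reuses \code{seed}. Give a
#'   transfer config the biologySeed of its training config and a fresh
#'   \code{seed} to simulate an unseen dataset of the same biology (see also
#'   [transferConfig()]).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(preset = c("easy", "hard", "transfer"),
                      nCells = 5000L, nGenes = 200L, imbalanceRatio = 100,
                      nMarkers = 20L, markerFoldChange = NULL,
                      baselineMeanLogMu = 0, baselineMeanLogSd = 1,
                      dispersion = NULL, librarySizeSd = 0.2, seed = 1L,
                      biologySeed = NA) {
  preset <- match.arg(preset)
  if (is.null(markerFoldChange))
    markerFoldChange <- if (preset == "hard") 2 else 8
  if (is.null(dispersion))
    dispersion <- if (preset == "hard") 1 else 2
  methods::new("SimConfig", biologySeed = as.integer(biologySeed),
               nCells = as.integer(nCells),
               nGenes = as.integer(nGenes),
               imbalanceRatio = as.numeric(imbalanceRatio),
               nMarkers = as.integer(nMarkers),
               markerFoldChange = as.numeric(markerFoldChange),
               baselineMeanLogMu = as.numeric(baselineMeanLogMu),
               baselineMeanLogSd = as.numeric(baselineMeanLogSd),
               dispersion = as.numeric(dispersion),
               librarySizeSd = as.numeric(librarySizeSd),
               separation = preset, seed = as.integer(seed))
}

#' Simulate an imbalanced single-cell count matrix with a rare cluster
#'
#' Generates a negative-binomial count background with lognormal gene means
#' and lognormal per-cell library scaling — the minimal generative structure
#' matching scRNA-seq overdispersion — plus one rare cluster whose marker
#' genes have their means multiplied by \code{markerFoldChange}. The minority
#' count is \code{round(nCells / (1 + imbalanceRatio))}; minority cells and
#' marker genes are placed at seeded random positions. Fully deterministic
#' per seed.
#'
#' @param cfg a [SimConfig-class].
#' @return list with elements \code{matrix} (raw [CountMatrix-class]),
#'   \code{labels} ([CellLabels-class]) and \code{markers} (character vector
#'   of true marker gene ids).
#' @export
simulateCounts <- function(cfg) {
  stopifnot(methods::is(cfg, "SimConfig"))
  nMin <- round(cfg@nCells / (1 + cfg@imbalanceRatio))
  if (nMin < 2) stop("configuration yields fewer than 2 minority cells")
  bioSeed <- if (is.na(cfg@biologySeed)) cfg@seed else cfg@biologySeed
  bio <- withSeed(bioSeed, {
    list(baseMu = stats::rlnorm(cfg@nGenes, cfg@baselineMeanLogMu,
                                cfg@baselineMeanLogSd),
         markerIdx = sort(sample.int(cfg@nGenes, cfg@nMarkers)))
  })
  withSeed(cfg@seed, {
    geneIds <- sprintf("gene_%04d", seq_len(cfg@nGenes))
    cellIds <- sprintf("cell_%05d", seq_len(cfg@nCells))
    baseMu <- bio$baseMu
    markerIdx <- bio$markerIdx
    libFactor <- stats::rlnorm(cfg@nCells, 0, cfg@librarySizeSd)
    minorityIdx <- sort(sample.int(cfg@nCells, nMin))
    label <- integer(cfg@nCells)
    label[minorityIdx] <- 1L
    fold <- rep(1, cfg@nGenes)
    fold[markerIdx] <- cfg@markerFoldChange
    mu <- outer(libFactor, baseMu)
    mu[minorityIdx, ] <- mu[minorityIdx, , drop = FALSE] *
      matrix(fold, nrow = nMin, ncol = cfg@nGenes, byrow = TRUE)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = cfg@dispersion),
                     nrow = cfg@nCells, ncol = cfg@nGenes,
                     dimnames = list(cellIds, geneIds))
    # the odd all-zero cell breaks log-normalization; give it one count
    empty <- rowSums(counts) == 0
    if (any(empty)) counts[empty, 1L] <- 1L
    list(matrix = countMatrix(counts, normalized = FALSE),
         labels = cellLabels(cellIds, label),
         markers = geneIds[markerIdx])
  })
}

#' Derive a transfer configuration from a training configuration
#'
#' Returns a config with the same gene-level biology (baseline means and
#' marker genes) as \code{cfg} but a fresh cell-level seed: an unseen dataset
#' of the same biology, the scenario a transferred annotator faces.
#'
#' @param cfg the training [SimConfig-class].
#' @param seed new cell-level seed.
#' @return a [SimConfig-class] with \code{separation = "transfer"}.
#' @export
transferConfig <- function(cfg, seed) {
  stopifnot(methods::is(cfg, "SimConfig"))
  bio <- if (is.na(cfg@biologySeed)) cfg@seed else cfg@biologySeed
  methods::initialize(cfg, separation = "transfer",
                      seed = as.integer(seed),
                      biologySeed = as.integer(bio))
}

#' Write a simulated dataset as an on-disk fixture
#'
#' Emits the full 10x-style triplet (\code{matrix.mtx}, \code{features.tsv},
#' \code{barcodes.tsv}), a two-column label file (\code{labels.tsv}, readable
#' by [readLabels()] with \code{positiveName = "rare"}) and the true marker
#' list (\code{markers.txt}), all round-trippable through the package
#' readers.
#'
#' @param sim output of [simulateCounts()].
#' @param directory output directory, created if needed.
#' @param gzip write gzipped variants of the triplet files.
#' @return the directory, invisibly.
#' @export
writeFixture <- function(sim, directory, gzip = FALSE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  writeMtxTriplet(sim$matrix, directory, gzip = gzip)
  type <- ifelse(sim$labels@label == 1L, "rare", "background")
  utils::write.table(data.frame(sim$labels@cellIds, type),
                     file.path(directory, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(sim$markers, file.path(directory, "markers.txt"))
  invisible(directory)
}

#' Serialize / deserialize a SimConfig as JSON
#'
#' @param cfg a [SimConfig-class].
#' @param path JSON file path.
#' @return \code{writeSimConfig}: the path, invisibly; \code{readSimConfig}:
#'   a [SimConfig-class].
#' @export
writeSimConfig <- function(cfg, path) {
  x <- list(preset = cfg@separation, nCells = cfg@nCells,
            nGenes = cfg@nGenes, imbalanceRatio = cfg@imbalanceRatio,
            nMarkers = cfg@nMarkers,
            markerFoldChange = cfg@markerFoldChange,
            baselineMeanLogMu = cfg@baselineMeanLogMu,
            baselineMeanLogSd = cfg@baselineMeanLogSd,
            dispersion = cfg@dispersion, librarySizeSd = cfg@librarySizeSd,
            seed = cfg@seed,
            biologySeed = if (is.na(cfg@biologySeed)) NULL
                          else cfg@biologySeed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  simConfig(preset = x$preset, nCells = x$nCells, nGenes = x$nGenes,
            imbalanceRatio = x$imbalanceRatio, nMarkers = x$nMarkers,
            markerFoldChange = x$markerFoldChange,
            baselineMeanLogMu = x$baselineMeanLogMu,
            baselineMeanLogSd = x$baselineMeanLogSd,
            dispersion = x$dispersion, librarySizeSd = x$librarySizeSd,
            seed = x$seed,
            biologySeed = if (is.null(x$biologySeed)) NA else x$biologySeed)
}
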