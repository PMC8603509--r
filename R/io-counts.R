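#' Read a 10x-style Matrix Market triplet directory
#'
#' Reads \code{matrix.mtx}, \code{features.tsv} (or \code{genes.tsv}) and
#' \code{barcodes.tsv} — plain or gzipped — from one directory. On disk the
#' 10x convention stores genes as rows and cells as columns; the matrix is
#' transposed on ingest so that cells are rows, the package's single
#' orientation.
#'
#' @param directory path containing the three files.
#' @return a [CountMatrix-class] with \code{normalized = FALSE}.
#' @export
readMtxTriplet <- function(directory) {
  mtx <- findTripletFile(directory, c("matrix.mtx"))
  feat <- findTripletFile(directory, c("features.tsv", "genes.tsv"))
  bc <- findTripletFile(directory, c("barcodes.tsv"))
  m <- Matrix::readMM(openMaybeGz(mtx))
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("empty matrix in ", mtx)
  genes <- utils::read.table(openMaybeGz(feat), sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(openMaybeGz(bc), sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes))
    stop(sprintf("matrix has %d rows but %d features listed", nrow(m),
                 length(genes)))
  if (ncol(m) != length(cells))
    stop(sprintf("matrix has %d columns but %d barcodes listed", ncol(m),
                 length(cells)))
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", feat)
  if (anyDuplicated(cells)) stop("duplicate cell ids in ", bc)
  m <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(m) <- list(cells, genes)
  methods::new("CountMatrix", counts = m, normalized = FALSE)
}

findTripletFile <- function(directory, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    p <- file.path(directory, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  stop("no ", paste(stems, collapse = "/"), " (or .gz) found in ", directory)
}

openMaybeGz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' Write a CountMatrix as a 10x-style triplet directory
#'
#' Writes \code{matrix.mtx}, \code{features.tsv} and \code{barcodes.tsv}
#' (genes-by-cells on disk, per the 10x convention).
#'
#' @param m a [CountMatrix-class].
#' @param directory output directory, created if needed.
#' @param gzip write gzipped variants of the three files.
#' @return the directory, invisibly.
#' @export
writeMtxTriplet <- function(m, directory, gzip = FALSE) {
  stopifnot(methods::is(m, "CountMatrix"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  mm <- Matrix::t(Matrix(m@counts, sparse = TRUE))
  mtx <- file.path(directory, "matrix.mtx")
  Matrix::writeMM(mm, mtx)
  writeLines(geneIds(m), file.path(directory, "features.tsv"))
  writeLines(cellIds(m), file.path(directory, "barcodes.tsv"))
  if (gzip) {
    for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv")) {
      p <- file.path(directory, f)
      gzCompressFile(p)
      unlink(p)
    }
  }
  invisible(directory)
}

gzCompressFile <- function(path) {
  con <- gzfile(paste0(path, ".gz"), "wb")
  on.exit(close(con))
  writeLines(readLines(path), con)
  invisible(paste0(path, ".gz"))
}

#' Read a dense delimited count matrix
#'
#' Reads a TSV/CSV with a header row of ids and an id column, in either
#' orientation; the result always has cells as rows.
#'
#' @param path file path (.csv is comma-separated, anything else tab).
#' @param orientation layout on disk: \code{"cells_x_genes"} (rows are cells)
#'   or \code{"genes_x_cells"}.
#' @param normalized whether the values are log-normalized rather than raw
#'   counts.
#' @return a [CountMatrix-class].
#' @export
readDense <- function(path, orientation = c("cells_x_genes", "genes_x_cells"),
                      normalized = FALSE) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(openMaybeGz(path), sep = sep, header = TRUE,
                          row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric entries in ", path)
  mat <- as.matrix(df)
  if (any(mat < 0)) stop("negative entries in ", path)
  if (orientation == "genes_x_cells") mat <- t(mat)
  countMatrix(mat, normalized = normalized)
}

#' Write a CountMatrix as dense TSV/CSV
#'
#' @param m a [CountMatrix-class].
#' @param path output path (.csv writes comma-separated).
#' @param orientation on-disk layout to write.
#' @return the path, invisibly.
#' @export
writeDense <- function(m, path,
                       orientation = c("cells_x_genes", "genes_x_cells")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  mat <- asDense(m@counts)
  if (orientation == "genes_x_cells") mat <- t(mat)
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell labels and binarize against a rare-type name
#'
#' Expects a headerless two-column table (cell id, cluster/type name). Cells
#' whose type equals \code{positiveName} get label 1 (minority/rare), all
#' others 0. An absent \code{positiveName} is an error so that an all-zero
#' label vector can never silently enter training.
#'
#' @param path two-column TSV path (plain or gzipped).
#' @param positiveName the rare cell type name.
#' @return a [CellLabels-class].
#' @export
readLabels <- function(path, positiveName) {
  df <- utils::read.table(openMaybeGz(path), sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("cell_id", "type"))
  if (anyDuplicated(df$cell_id)) stop("duplicate cell ids in ", path)
  if (!positiveName %in% df$type)
    stop("positive type '", positiveName, "' not present in ", path)
  cellLabels(df$cell_id, as.integer(df$type == positiveName))
}

#' Read a marker gene list (one gene symbol per line)
#'
#' @param path text file path (plain or gzipped).
#' @return character vector of gene ids.
#' @export
readMarkerList <- function(path) {
  x <- readLines(openMaybeGz(path))
  x <- trimws(x)
  x[nzchar(x)]
}

#' Log-normalize raw counts
#'
#' Per-cell library-size normalization followed by a log transform:
#' \code{log(1 + count / total_counts(cell) * scaleFactor)} with the natural
#' logarithm, the standard LogNormalize transform with scale factor 10000.
#' Sparsity is preserved (zero counts map to exactly zero).
#'
#' @param m raw-count [CountMatrix-class].
#' @param scaleFactor positive scale factor (default 10000).
#' @return a [CountMatrix-class] with \code{normalized = TRUE}.
#' @export
logNormalize <- function(m, scaleFactor = 10000) {
  stopifnot(methods::is(m, "CountMatrix"))
  if (m@normalized) stop("matrix is already normalized")
  if (scaleFactor <= 0) stop("scaleFactor must be positive")
  totals <- Matrix::rowSums(m@counts)
  if (any(totals <= 0))
    stop(sum(totals <= 0), " cell(s) with zero total counts")
  x <- m@counts
  if (methods::is(x, "sparseMatrix")) {
    x <- methods::as(x, "CsparseMatrix")
    # dgCMatrix: @i holds 0-based row indices of the stored entries
    x@x <- log1p(x@x * scaleFactor / totals[x@i + 1L])
  } else {
    x <- log1p(x * scaleFactor / totals)
  }
  methods::new("CountMatrix", counts = x, normalized = TRUE)
}

#' Align a matrix with labels and restrict to selected genes
#'
#' Matches cells by id (intersection, preserving the matrix order) and
#' restricts columns to \code{genes} in the requested order. Labels covering
#' extra cells are dropped with a warning. Genes absent from the matrix are
#' handled per \code{missingGenes}: \code{"zero_fill"} (default) inserts a
#' zero column with a warning — tolerant of gene-annotation drift when
#' transferring a model to an unseen dataset — while \code{"error"} aborts.
#'
#' @param m a [CountMatrix-class].
#' @param labels a [CellLabels-class].
#' @param genes character vector of gene ids to keep, in order.
#' @param missingGenes policy for requested genes absent from \code{m}.
#' @return a [LabeledDataset-class].
#' @export
alignAndSubset <- function(m, labels, genes,
                           missingGenes = c("zero_fill", "error")) {
  missingGenes <- match.arg(missingGenes)
  stopifnot(methods::is(m, "CountMatrix"), methods::is(labels, "CellLabels"))
  genes <- as.character(genes)
  if (!length(genes)) stop("no genes requested")
  ids <- cellIds(m)
  keep <- ids %in% labels@cellIds
  if (!any(keep)) stop("no cell ids shared between matrix and labels")
  if (!all(keep))
    logWarn("%d matrix cell(s) without labels dropped", sum(!keep))
  extra <- sum(!labels@cellIds %in% ids)
  if (extra > 0)
    logWarn("%d label row(s) without matching cells dropped", extra)
  ids <- ids[keep]
  lab <- labels@label[match(ids, labels@cellIds)]
  present <- genes %in% geneIds(m)
  if (!any(present)) stop("none of the requested genes are present")
  if (!all(present)) {
    if (missingGenes == "error")
      stop("missing genes: ", paste(genes[!present], collapse = ", "))
    logWarn("%d requested gene(s) absent; zero-filled: %s", sum(!present),
            paste(genes[!present], collapse = ", "))
  }
  feat <- matrix(0, nrow = length(ids), ncol = length(genes),
                 dimnames = list(ids, genes))
  feat[, genes[present]] <- asDense(m@counts[keep, genes[present],
                                             drop = FALSE])
  labeledDataset(feat, lab, normalized = m@normalized)
}
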