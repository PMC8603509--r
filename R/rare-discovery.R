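#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN with Euclidean distances: a core point has at least
#' \code{minSize} points (itself included) within radius \code{eps}; clusters
#' are the connected components of core points together with the border
#' points they reach; everything else is noise (label -1). The textbook
#' algorithm leaves border points reachable from several clusters ambiguous;
#' here the rule is fixed: clusters are numbered by the row order of their
#' first core point, and a border point joins the cluster of its
#' smallest-row-index core neighbor, so the result is fully reproducible.
#'
#' @param x numeric feature matrix (cells x features).
#' @param eps positive neighborhood radius.
#' @param minSize minimum cluster size; the point itself counts.
#' @return a [DensityClustering-class] with labels -1 (noise) or 0..C-1.
#' @export
dbscanCluster <- function(x, eps, minSize = 5L) {
  x <- asDense(x)
  if (eps <= 0) stop("eps must be positive")
  if (minSize < 1L) stop("minSize must be >= 1")
  n <- nrow(x)
  if (n < 1L) stop("empty matrix")
  d2 <- pairwiseSq(x, x)
  eps2 <- eps^2
  nbrs <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps2))
  core <- lengths(nbrs) >= minSize
  labels <- rep(-1L, n)
  # connected components of core points, numbered in row order of discovery
  cl <- -1L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      for (q in nbrs[[j]]) {
        if (core[q] && labels[q] == -1L) {
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  # border points join the cluster of their smallest-row-index core neighbor
  for (i in seq_len(n)) {
    if (core[i]) next
    cn <- nbrs[[i]][core[nbrs[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("cell_", seq_len(n))
  methods::new("DensityClustering", cellIds = ids, labels = labels,
               eps = as.numeric(eps), minSize = as.integer(minSize))
}

#' Unsupervised rare-cluster discovery via Gini-selected markers and DBSCAN
#'
#' The GiniClust-style baseline the supervised pipeline is compared against:
#' restrict the matrix to a supplied marker list, compute the Gini index of
#' each marker across cells, min-max normalize the indices, keep the
#' \code{topM} most unequal (highest normalized Gini) genes, and run DBSCAN
#' on the cells in that gene subspace. A rare population that is dense and
#' well separated in marker space comes out as a small cluster; a diffuse one
#' falls below core density and is labeled noise — the failure mode that
#' motivates supervised annotation.
#'
#' @param m a [CountMatrix-class] (the same normalized scale as the
#'   supervised arm is recommended).
#' @param markers candidate marker gene ids.
#' @param topM number of markers kept after Gini ranking (default 15).
#' @param eps DBSCAN radius (default 0.5).
#' @param minSize DBSCAN minimum cluster size (default 5).
#' @param missingGenes policy for markers absent from \code{m}.
#' @return a [DensityClustering-class] over the cells of \code{m}.
#' @export
giniDbscan <- function(m, markers, topM = 15L, eps = 0.5, minSize = 5L,
                       missingGenes = c("zero_fill", "error")) {
  missingGenes <- match.arg(missingGenes)
  stopifnot(methods::is(m, "CountMatrix"))
  markers <- as.character(markers)
  if (topM > length(markers))
    stop("topM (", topM, ") exceeds the ", length(markers),
         " supplied markers")
  present <- markers %in% geneIds(m)
  if (!any(present)) stop("none of the markers are present")
  if (!all(present)) {
    if (missingGenes == "error")
      stop("missing markers: ", paste(markers[!present], collapse = ", "))
    logWarn("%d marker(s) absent; zero-filled: %s", sum(!present),
            paste(markers[!present], collapse = ", "))
  }
  x <- matrix(0, nrow = nrow(m@counts), ncol = length(markers),
              dimnames = list(cellIds(m), markers))
  x[, markers[present]] <- asDense(m@counts[, markers[present],
                                            drop = FALSE])
  g <- apply(x, 2, giniIndex)
  gn <- normalizeGini(g)
  keep <- markers[order(-gn, markers)][seq_len(topM)]
  dbscanCluster(x[, keep, drop = FALSE], eps = eps, minSize = minSize)
}

#' Write a clustering as two-column TSV (cell id, cluster label)
#'
#' @param dc a [DensityClustering-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeClustering <- function(dc, path) {
  utils::write.table(data.frame(cell_id = dc@cellIds, cluster = dc@labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
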