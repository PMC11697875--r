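#' Build labeled neighborhood graphs from a per-cell spatial table
#'
#' Constructs one \code{\link{SpatialGraph}} per section from a table of
#' cell coordinates and cell-type labels. Edges connect spatially adjacent
#' cells according to the chosen method:
#' \describe{
#'   \item{delaunay}{cells sharing an edge of the Delaunay triangulation
#'     (2D only); the default, parameter-free choice.}
#'   \item{knn}{undirected union of each cell's \code{param} nearest
#'     neighbors (Euclidean).}
#'   \item{epsilon}{cells within distance \code{param} of each other.}
#' }
#' Every method is label-agnostic: the edge set depends only on coordinates.
#'
#' Cell types are mapped to a contiguous integer code \code{1..L} shared
#' across sections (code 0 is reserved for erased nodes). Exact duplicate
#' coordinates within a section raise an error unless
#' \code{jitterDuplicates = TRUE}, which applies a deterministic, seeded
#' jitter of magnitude 1e-6 times the bounding-box diagonal; silent
#' perturbation is never applied.
#'
#' @param cells data.frame with columns \code{x}, \code{y} (optionally
#'   \code{z}), \code{cell_type}, and optionally \code{section} (default
#'   one section "S1") and \code{cell_id}.
#' @param method one of "delaunay", "knn", "epsilon".
#' @param param K (integer >= 1) for knn; radius (> 0) for epsilon;
#'   ignored for delaunay.
#' @param maxEdgeLength optional upper bound on edge length; edges longer
#'   than this are dropped (off by default).
#' @param jitterDuplicates opt-in deterministic jitter for duplicate
#'   coordinates.
#' @param seed seed for the jitter (only used when jittering).
#' @return named list of \code{SpatialGraph}, one per section.
#' @examples
#' cells <- data.frame(x = c(0, 2, 1), y = c(0, 0, 2),
#'                     cell_type = c("A", "B", "A"))
#' g <- buildGraph(cells, method = "delaunay")[[1]]
#' graphEdges(g)  # the single triangle
#' @export
buildGraph <- function(cells, method = c("delaunay", "knn", "epsilon"),
                       param = NULL, maxEdgeLength = NULL,
                       jitterDuplicates = FALSE, seed = 1L) {
  method <- match.arg(method)
  cells <- as.data.frame(cells)
  need <- c("x", "y", "cell_type")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"section" %in% names(cells)) cells$section <- "S1"
  dims <- if ("z" %in% names(cells) && !all(is.na(cells$z))) 3L else 2L

  fac <- factor(cells$cell_type)
  typeNames <- levels(fac)
  codes <- as.integer(fac)

  if (method == "knn") {
    if (is.null(param) || param < 1) stop("knn requires param = K >= 1")
    param <- as.integer(param)
  } else if (method == "epsilon") {
    if (is.null(param) || param <= 0) stop("epsilon requires param = radius > 0")
  } else {
    if (dims == 3L)
      stop("delaunay graph construction supports 2D coordinates only; ",
           "use method = 'knn' or 'epsilon' for 3D data")
    param <- NA_real_
  }

  out <- list()
  for (sec in unique(as.character(cells$section))) {
    idx <- which(as.character(cells$section) == sec)
    xy <- cbind(cells$x[idx], cells$y[idx])
    if (dims == 3L) xy <- cbind(xy, cells$z[idx])
    ids <- if ("cell_id" %in% names(cells)) as.character(cells$cell_id[idx])
           else as.character(seq_along(idx))
    if (anyDuplicated(ids))
      stop("duplicate cell_id within section '", sec, "'")
    xy <- resolveDuplicates(xy, sec, jitterDuplicates,
                            deriveSeed(seed, "graph", match(sec, unique(cells$section))))
    edges <- switch(method,
      delaunay = delaunayEdges(xy, sec),
      knn      = knnEdges(xy, param),
      epsilon  = epsilonEdges(xy, param))
    if (!is.null(maxEdgeLength)) {
      len <- sqrt(rowSums((xy[edges[, 1L], , drop = FALSE] -
                           xy[edges[, 2L], , drop = FALSE])^2))
      edges <- edges[len <= maxEdgeLength, , drop = FALSE]
    }
    out[[sec]] <- newSpatialGraph(xy, codes[idx], typeNames, edges, sec,
                                  method, param, ids)
  }
  out
}

resolveDuplicates <- function(xy, sec, jitter, seed) {
  if (!anyDuplicated(xy)) return(xy)
  if (!jitter)
    stop("section '", sec, "' contains cells with identical coordinates; ",
         "set jitterDuplicates = TRUE for a deterministic seeded jitter")
  bbox <- sqrt(sum((apply(xy, 2, max) - apply(xy, 2, min))^2))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  dup <- duplicated(xy)
  xy[dup, ] <- xy[dup, , drop = FALSE] +
    matrix(stats::runif(sum(dup) * ncol(xy), -1, 1), ncol = ncol(xy)) *
      1e-6 * bbox
  xy
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

delaunayEdges <- function(xy, sec) {
  if (nrow(xy) < 3)
    stop("delaunay requires at least 3 points (section '", sec, "')")
  rngx <- range(xy[, 1]); rngy <- range(xy[, 2])
  tr <- tryCatch(
    deldir::deldir(xy[, 1], xy[, 2],
                   rw = c(rngx[1] - 1, rngx[2] + 1, rngy[1] - 1, rngy[2] + 1)),
    error = function(e)
      stop("degenerate Delaunay input in section '", sec, "': ",
           conditionMessage(e), call. = FALSE))
  e <- cbind(tr$delsgs$ind1, tr$delsgs$ind2)
  if (nrow(e) == 0 || !isTRUE(tr$del.area > 0))
    stop("degenerate (collinear?) Delaunay input in section '", sec, "'")
  canonicalEdges(e)
}

knnEdges <- function(xy, K) {
  n <- nrow(xy)
  kk <- min(K + 1L, n)
  nn <- RANN::nn2(xy, xy, k = kk)
  from <- rep(seq_len(n), each = kk)
  to <- as.vector(t(nn$nn.idx))
  keep <- from != to
  canonicalEdges(cbind(from[keep], to[keep]))
}

epsilonEdges <- function(xy, radius) {
  n <- nrow(xy)
  kcap <- min(n, 1024L)
  nn <- RANN::nn2(xy, xy, k = kcap, searchtype = "radius", radius = radius)
  if (kcap < n && any(nn$nn.idx[, kcap] != 0))
    warning("epsilon graph: some vertices have more than ", kcap - 1,
            " neighbors within the radius; edge list may be truncated")
  from <- rep(seq_len(n), times = kcap)
  to <- as.vector(nn$nn.idx)
  keep <- to != 0L & from != to
  canonicalEdges(cbind(from[keep], to[keep]))
}

canonicalEdges <- function(e) {
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e[e[, 1L] != e[, 2L], , drop = FALSE])
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  storage.mode(e) <- "integer"
  e
}

newSpatialGraph <- function(coords, labels, typeNames, edges, section,
                            method = "manual", param = NA_real_,
                            cellIds = character()) {
  n <- nrow(coords)
  adj <- buildAdjacency(edges, n)
  new("SpatialGraph", section = section, coords = coords,
      labels = as.integer(labels), typeNames = typeNames, edges = edges,
      adj = adj, method = method, param = as.numeric(param),
      cellIds = if (length(cellIds)) cellIds else as.character(seq_len(n)))
}

buildAdjacency <- function(edges, n) {
  adj <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    ends <- c(edges[, 2L], edges[, 1L])
    src <- c(edges[, 1L], edges[, 2L])
    sp <- split(ends, factor(src, levels = seq_len(n)))
    adj <- lapply(sp, function(v) sort(v))
  }
  adj
}

#' Construct a SpatialGraph from explicit components
#'
#' Low-level constructor used by tests and simulations; most users should
#' call \code{\link{buildGraph}} on a cell table.
#'
#' @param coords numeric matrix (n x 2 or n x 3).
#' @param labels integer cell-type codes (0 allowed for erased).
#' @param edges two-column integer matrix of undirected edges (any
#'   orientation; canonicalized internally).
#' @param typeNames code-to-name table; defaults to character codes.
#' @param section section identifier.
#' @return a \code{SpatialGraph}
#' @export
spatialGraph <- function(coords, labels, edges,
                         typeNames = as.character(seq_len(max(labels, 1))),
                         section = "S1") {
  coords <- as.matrix(coords)
  edges <- canonicalEdges(as.matrix(edges))
  newSpatialGraph(coords, labels, typeNames, edges, section)
}

#' Forward neighborhood of a vertex
#'
#' The set of vertices adjacent to \code{v} that are not in the excluded
#' set: the candidate extensions of a growing path rooted earlier.
#'
#' @param g a \code{\link{SpatialGraph}}
#' @param v vertex index
#' @param excluded integer vector of excluded vertices (may be empty)
#' @return sorted integer vector of neighbors of \code{v} not excluded
#' @examples
#' g <- spatialGraph(cbind(c(0, 2, 1), c(0, 0, 2)), c(1, 1, 1),
#'                   rbind(c(1, 2), c(2, 3), c(1, 3)))
#' forwardNeighborhood(g, 1, integer(0))  # 2 3
#' forwardNeighborhood(g, 1, c(2, 3))     # integer(0)
#' @export
forwardNeighborhood <- function(g, v, excluded = integer(0)) {
  stopifnot(is(g, "SpatialGraph"))
  v <- as.integer(v)
  if (length(v) != 1L || is.na(v) || v < 1L || v > nCells(g))
    stop("vertex ", v, " is not in the graph")
  setdiff(g@adj[[v]], as.integer(excluded))
}

#' Read a per-cell spatial table from CSV/TSV
#'
#' Delimited text with required columns \code{x}, \code{y} (optionally
#' \code{z}), \code{cell_type}, and optionally \code{section} and
#' \code{cell_id}. Any additional numeric columns are preserved (e.g. gene
#' counts). Malformed input is rejected with the offending column named.
#'
#' @param path file path (delimiter sniffed by \code{data.table::fread}).
#' @return data.frame of cells
#' @export
readCellTable <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  for (col in c("x", "y", "cell_type")) {
    if (!col %in% names(df))
      stop("input '", path, "' is missing required column '", col, "'")
  }
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("columns x and y must be numeric in '", path, "'")
  df
}

#' Write a graph as node and edge tables
#'
#' Node table columns: index (0-based, as documented for the file
#' boundary; internal indices are 1-based), coordinates, label, section.
#' Edge table columns: v1, v2 (0-based).
#'
#' @param g a \code{\link{SpatialGraph}}
#' @param nodeFile,edgeFile output TSV paths
#' @return invisibly, the two paths
#' @export
writeGraph <- function(g, nodeFile, edgeFile) {
  stopifnot(is(g, "SpatialGraph"))
  co <- spatialCoords(g)
  nodes <- data.frame(index = seq_len(nCells(g)) - 1L, x = co[, 1], y = co[, 2])
  if (ncol(co) == 3) nodes$z <- co[, 3]
  nodes$label <- cellLabels(g)
  nodes$section <- sectionId(g)
  data.table::fwrite(nodes, nodeFile, sep = "\t")
  e <- graphEdges(g)
  data.table::fwrite(data.frame(v1 = e[, 1L] - 1L, v2 = e[, 2L] - 1L),
                     edgeFile, sep = "\t")
  invisible(c(nodeFile, edgeFile))
}
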