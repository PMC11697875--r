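#' Enumerate all simple k-node paths of a graph (PEN)
#'
#' Systematically generates every simple path of \code{k} nodes, extending
#' a growing path only through vertices adjacent to the newly added tail
#' that are not already on the path. Each undirected path is reported once,
#' in canonical orientation (index of the last vertex greater than that of
#' the first). With \code{radial = TRUE} only radial paths are kept: paths
#' along which physical distance monotonically increases along the node
#' sequence (see \code{\link{isRadial}}).
#'
#' @param g a \code{\link{SpatialGraph}}
#' @param k path length in nodes (>= 2); \code{k > nCells(g)} yields an
#'   empty set.
#' @param radial restrict to radial paths?
#' @param radialMode "symmetric" (default; a path is radial iff its reverse
#'   is) or "forward" (distance from the start node only).
#' @return a \code{\link{PathSet}}
#' @examples
#' g <- spatialGraph(cbind(0:2, c(0, 0, 0)), rep(1, 3),
#'                   rbind(c(1, 2), c(2, 3)))
#' pathNodes(enumeratePaths(g, 3))  # the single path 1-2-3
#' @export
enumeratePaths <- function(g, k, radial = FALSE,
                           radialMode = c("symmetric", "forward", "pairwise")) {
  samplePathsInternal(g, k, rep(1, k), radial, match.arg(radialMode))
}

#' Uniformly sample simple paths (URPEN)
#'
#' Partial exploration of the PEN recursion tree: the extension to depth
#' \code{d} is traversed with probability \code{prob[d]}, so every k-node
#' path is included with identical probability \code{prod(prob)} --
#' uniform sampling without the bias of random walks. \code{prob[1]}
#' applies to root-vertex inclusion. A scalar \code{level} is expanded to
#' \code{c(1, ..., 1, level)}, matching the usual usage where only the last
#' extension is subsampled.
#'
#' @param g a \code{\link{SpatialGraph}}
#' @param k path length in nodes (>= 2)
#' @param level scalar sampling level in [0,1]; ignored when \code{prob}
#'   is given.
#' @param prob full per-depth probability vector of length \code{k}.
#' @param radial restrict to radial paths?
#' @param radialMode see \code{\link{enumeratePaths}}.
#' @param seed integer seed (master seed; the RNG stream is derived from it
#'   by a fixed rule so section-parallel runs are reproducible).
#' @return a \code{\link{PathSet}}
#' @export
samplePaths <- function(g, k, level = 1, prob = NULL, radial = TRUE,
                        radialMode = c("symmetric", "forward", "pairwise"), seed = 1L) {
  if (is.null(prob)) prob <- c(rep(1, k - 1), level)
  if (length(prob) != k)
    stop("prob must have length k = ", k)
  if (any(prob < 0) || any(prob > 1))
    stop("all per-depth probabilities must lie in [0, 1]")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(deriveSeed(seed, "sample"))
  samplePathsInternal(g, k, prob, radial, match.arg(radialMode))
}

samplePathsInternal <- function(g, k, prob, radial, radialMode) {
  stopifnot(is(g, "SpatialGraph"))
  k <- as.integer(k)
  if (k < 2L) stop("path length k must be at least 2")
  if (k > nCells(g)) {
    nodes <- matrix(integer(0), 0, k)
  } else {
    mode <- if (!radial) 0L
            else switch(radialMode, symmetric = 1L, forward = 2L,
                        pairwise = 3L)
    nodes <- cpp_pen(g@adj, k, as.numeric(prob), g@coords, mode)
  }
  new("PathSet", section = g@section, nodes = nodes, k = k,
      radial = isTRUE(radial), prob = as.numeric(prob))
}

#' Test the radial condition for one node sequence
#'
#' A path is radial when physical distance monotonically increases along
#' its node sequence, so that nodes far apart in the path are far apart in
#' space. The default symmetric criterion requires the Euclidean distance
#' from the first node to increase strictly along the sequence AND the
#' distance from the last node to increase strictly along the reversed
#' sequence; under it a path is radial iff its reverse is. Ties (exactly
#' equal distances) fail. Any 2-node path is radial.
#'
#' @param nodes integer vector of vertex indices (ordered path)
#' @param coords coordinate matrix indexed by vertex
#' @param mode "symmetric" (default), "forward" (start-node chain only) or
#'   "pairwise" (every node's distance to every other node strictly
#'   increases with their separation along the path, in both directions --
#'   the strictest reading, under which path order and spatial order agree
#'   for all pairs)
#' @return logical
#' @export
isRadial <- function(nodes, coords,
                     mode = c("symmetric", "forward", "pairwise")) {
  mode <- match.arg(mode)
  nodes <- as.integer(nodes)
  if (length(nodes) < 2L) stop("a path needs at least 2 nodes")
  xy <- coords[nodes, , drop = FALSE]
  if (anyNA(xy)) stop("missing coordinates for path nodes")
  k <- length(nodes)
  if (mode == "pairwise") {
    D <- as.matrix(stats::dist(xy))
    for (i in seq_len(k)) {
      if (i < k && any(diff(D[i, i:k]) <= 0)) return(FALSE)
      if (i > 1 && any(diff(D[i, i:1]) <= 0)) return(FALSE)
    }
    return(TRUE)
  }
  dFirst <- sqrt(colSums((t(xy) - xy[1L, ])^2))
  if (any(diff(dFirst) <= 0)) return(FALSE)
  if (mode == "forward") return(TRUE)
  dLast <- sqrt(colSums((t(xy) - xy[k, ])^2))
  all(diff(rev(dLast)) > 0)
}

#' Add reverse paths to a path set
#'
#' Motif occurrences are orientation-free, so after sampling each canonical
#' path its reversal (nodes and label word reversed) is incorporated into
#' the dataset. Since a simple path of >= 2 distinct nodes is never its own
#' reverse, the output has exactly twice as many rows.
#'
#' @param ps a \code{\link{PathSet}} in canonical orientation
#' @return a \code{\link{PathSet}} with reversed rows appended
#' @export
addReverses <- function(ps) {
  stopifnot(is(ps, "PathSet"))
  nd <- ps@nodes
  if (nrow(nd) == 0) return(ps)
  new("PathSet", section = ps@section,
      nodes = rbind(nd, nd[, ps@k:1, drop = FALSE]),
      k = ps@k, radial = ps@radial, prob = ps@prob)
}

#' Label words of a path set
#'
#' @param ps a \code{\link{PathSet}}
#' @param g the source \code{\link{SpatialGraph}} supplying labels
#' @return integer matrix of cell-type codes, one word per row
#' @export
pathWords <- function(ps, g) {
  stopifnot(is(ps, "PathSet"), is(g, "SpatialGraph"))
  m <- cellLabels(g)[ps@nodes]
  dim(m) <- dim(ps@nodes)
  m
}

#' Write sampled paths as TSV
#'
#' Columns: section, node_1..node_k (0-based at the file boundary),
#' label_word (dash-separated type codes).
#'
#' @param ps a \code{\link{PathSet}}
#' @param g source graph (for labels)
#' @param path output file
#' @return invisibly, the path
#' @export
writePaths <- function(ps, g, path) {
  w <- pathWords(ps, g)
  df <- as.data.frame(ps@nodes - 1L)
  names(df) <- paste0("node_", seq_len(ps@k))
  df <- cbind(section = ps@section, df,
              label_word = apply(w, 1, paste, collapse = "-"))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
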