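#' @import methods
NULL

#' Labeled spatial neighborhood graph for one tissue section
#'
#' A \code{SpatialGraph} holds the cells of a single section (or animal ID)
#' as vertices indexed \code{1..n}, together with their spatial coordinates,
#' integer cell-type labels, and the undirected edge set of the neighborhood
#' graph. Label code 0 is reserved for "erased" cells (nodes consumed by a
#' previously discovered motif); real cell types are \code{1..L} with a
#' code-to-name table in \code{typeNames}.
#'
#' @slot section section / animal identifier, length-1 character.
#' @slot coords numeric matrix, one row per cell, 2 or 3 columns (microns).
#' @slot labels integer vector of cell-type codes, 0 = erased.
#' @slot typeNames character vector mapping code \code{i} to a type name.
#' @slot edges integer matrix with two columns; each row is an undirected
#'   edge with \code{edges[,1] < edges[,2]}, no duplicates, no self-loops.
#' @slot adj adjacency list (list of sorted integer vectors), derived from
#'   \code{edges} at construction time.
#' @slot method graph construction method ("delaunay", "knn", "epsilon").
#' @slot param numeric parameter of the method (K or radius; NA for delaunay).
#' @slot cellIds optional per-cell identifiers.
#'
#' @seealso \code{\link{buildGraph}}, \code{\link{cellLabels}}
#' @export
setClass("SpatialGraph",
  representation(
    section  = "character",
    coords   = "matrix",
    labels   = "integer",
    typeNames = "character",
    edges    = "matrix",
    adj      = "list",
    method   = "character",
    param    = "numeric",
    cellIds  = "character"
  )
)

setValidity("SpatialGraph", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (!ncol(object@coords) %in% c(2L, 3L))
    msg <- c(msg, "coords must have 2 or 3 columns")
  if (length(object@labels) != n)
    msg <- c(msg, "labels length must equal number of coordinate rows")
  L <- length(object@typeNames)
  if (n > 0 && (min(object@labels) < 0L || max(object@labels) > L))
    msg <- c(msg, sprintf("labels must lie in 0..%d", L))
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0) {
    if (min(e) < 1L || max(e) > n)
      msg <- c(msg, "edge endpoints out of vertex range")
    if (any(e[, 1L] >= e[, 2L]))
      msg <- c(msg, "edges must satisfy v1 < v2 (no self-loops)")
    if (anyDuplicated(e))
      msg <- c(msg, "duplicate edges")
  }
  if (length(object@adj) != n)
    msg <- c(msg, "adjacency list length must equal n")
  if (length(msg)) msg else TRUE
})

#' A set of simple paths sampled from one SpatialGraph
#'
#' Rows of \code{nodes} are ordered vertex tuples of fixed length \code{k};
#' all vertices within a row are distinct and consecutive vertices are
#' adjacent in the source graph. Paths produced by enumeration are stored in
#' canonical orientation (last vertex index greater than the first);
#' \code{\link{addReverses}} doubles the set with the reversed rows.
#'
#' @slot section section identifier of the source graph.
#' @slot nodes integer matrix, one path per row, \code{k} columns.
#' @slot k path length in nodes.
#' @slot radial logical; were paths restricted to the radial condition?
#' @slot prob per-depth traversal probabilities used by URPEN
#'   (all ones for exhaustive enumeration).
#' @export
setClass("PathSet",
  representation(
    section = "character",
    nodes   = "matrix",
    k       = "integer",
    radial  = "logical",
    prob    = "numeric"
  )
)

setValidity("PathSet", function(object) {
  msg <- character()
  if (nrow(object@nodes) > 0 && ncol(object@nodes) != object@k)
    msg <- c(msg, "nodes must have k columns")
  if (length(object@prob) && (any(object@prob < 0) || any(object@prob > 1)))
    msg <- c(msg, "prob entries must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Position weight matrix over cell types
#'
#' Column-stochastic L x W matrix: column j gives the cell-type distribution
#' at motif position j. Carries the background frequency vector and the
#' Dirichlet prior weight used to regularize it.
#'
#' @slot mat numeric L x W matrix; every column sums to 1.
#' @slot background numeric length-L background frequencies (sum 1).
#' @slot rho Dirichlet prior weight (default 0.01).
#' @export
setClass("Pwm",
  representation(mat = "matrix", background = "numeric", rho = "numeric")
)

setValidity("Pwm", function(object) {
  msg <- character()
  if (nrow(object@mat) != length(object@background))
    msg <- c(msg, "background length must equal number of PWM rows")
  cs <- colSums(object@mat)
  if (length(cs) && any(abs(cs - 1) > 1e-9))
    msg <- c(msg, "PWM columns must sum to 1 (tolerance 1e-9)")
  if (any(object@mat < 0))
    msg <- c(msg, "PWM entries must be non-negative")
  if (object@rho < 0) msg <- c(msg, "rho must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A discovered spatial motif
#'
#' Final state of one discovery round: the refined PWM, the member seeds
#' (words above the selected PWM-score threshold, with their incremental and
#' total ZNIC counts and initial-evaluation log p-values), the training and
#' hold-out score log10 p-values, and the graph nodes occupied by the
#' motif's node-disjoint occurrences.
#'
#' @slot pwm the motif \code{\link{Pwm}}.
#' @slot consensus integer consensus word (per-column argmax of the PWM).
#' @slot members data.frame with columns word (string), wordId, Z
#'   (incremental ZNIC count), N (total ZNIC count), P (initial log10 p),
#'   score (PWM likelihood-ratio score).
#' @slot scoreThreshold PWM score cutoff selected by enrichment.
#' @slot logPTrain training log10 p-value at the selected cutoff.
#' @slot logPScore hold-out log10 p-value (95th-percentile least significant
#'   over the score replicates).
#' @slot occupiedNodes named list, section -> integer vector of vertices in
#'   the motif's selected occurrences.
#' @slot positionNodes list of length W; element j holds the global cell
#'   indices (concatenated-section order) occupying motif position j in the
#'   selected occurrences. Used by the differential-expression module.
#' @slot rank discovery order (1 = first motif found).
#' @export
setClass("SpatialMotif",
  representation(
    pwm = "Pwm",
    consensus = "integer",
    members = "data.frame",
    scoreThreshold = "numeric",
    logPTrain = "numeric",
    logPScore = "numeric",
    occupiedNodes = "list",
    positionNodes = "list",
    rank = "integer"
  )
)

#' @describeIn SpatialGraph-class compact display
#' @param object a \code{SpatialGraph}
#' @export
setMethod("show", "SpatialGraph", function(object) {
  cat(sprintf(
    "SpatialGraph '%s': %d cells (%dD), %d edges, %d cell types [%s]\n",
    object@section, nrow(object@coords), ncol(object@coords),
    nrow(object@edges), length(object@typeNames), object@method))
})

#' @describeIn PathSet-class compact display
#' @param object a \code{PathSet}
#' @export
setMethod("show", "PathSet", function(object) {
  cat(sprintf("PathSet '%s': %d paths of length %d (%s)\n",
    object@section, nrow(object@nodes), object@k,
    if (isTRUE(object@radial)) "radial" else "unconstrained"))
})

#' @describeIn Pwm-class compact display
#' @param object a \code{Pwm}
#' @export
setMethod("show", "Pwm", function(object) {
  cat(sprintf("Pwm: %d types x %d positions, rho = %g\n",
    nrow(object@mat), ncol(object@mat), object@rho))
  print(round(object@mat, 3))
})

#' @describeIn SpatialMotif-class compact display
#' @param object a \code{SpatialMotif}
#' @export
setMethod("show", "SpatialMotif", function(object) {
  cat(sprintf(
    "SpatialMotif #%d  consensus %s  logP(train) %.2f  logP(score) %.2f  %d seeds\n",
    object@rank, paste(object@consensus, collapse = "-"),
    object@logPTrain, object@logPScore, nrow(object@members)))
})
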