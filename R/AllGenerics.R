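#' Number of cells (vertices) in a graph
#' @param x a \code{\link{SpatialGraph}}
#' @return integer count
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "SpatialGraph", function(x) nrow(x@coords))

#' Cell-type code-to-name table
#' @param x a \code{\link{SpatialGraph}}
#' @return character vector; element \code{i} names type code \code{i}
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "SpatialGraph", function(x) x@typeNames)

#' Per-cell integer type labels (0 = erased)
#' @param x a \code{\link{SpatialGraph}}
#' @return integer vector of length \code{nCells(x)}
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname cellLabels
#' @export
setMethod("cellLabels", "SpatialGraph", function(x) x@labels)

#' @rdname cellLabels
#' @param value replacement integer label vector
#' @export
setGeneric("cellLabels<-", function(x, value) standardGeneric("cellLabels<-"))

#' @rdname cellLabels
#' @export
setMethod("cellLabels<-", "SpatialGraph", function(x, value) {
  x@labels <- as.integer(value)
  validObject(x)
  x
})

#' Undirected edge matrix of a graph
#' @param x a \code{\link{SpatialGraph}}
#' @return two-column integer matrix, \code{v1 < v2} per row
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname graphEdges
#' @export
setMethod("graphEdges", "SpatialGraph", function(x) x@edges)

#' Spatial coordinates of the cells
#' @param x a \code{\link{SpatialGraph}}
#' @return numeric matrix (n x 2 or n x 3)
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname spatialCoords
#' @export
setMethod("spatialCoords", "SpatialGraph", function(x) x@coords)

#' Section identifier
#' @param x a \code{\link{SpatialGraph}} or \code{\link{PathSet}}
#' @return length-1 character
#' @export
setGeneric("sectionId", function(x) standardGeneric("sectionId"))

#' @rdname sectionId
#' @export
setMethod("sectionId", "SpatialGraph", function(x) x@section)

#' @rdname sectionId
#' @export
setMethod("sectionId", "PathSet", function(x) x@section)

#' Node matrix of a path set
#' @param x a \code{\link{PathSet}}
#' @return integer matrix, one path per row
#' @export
setGeneric("pathNodes", function(x) standardGeneric("pathNodes"))

#' @rdname pathNodes
#' @export
setMethod("pathNodes", "PathSet", function(x) x@nodes)

#' Number of paths in a path set
#' @param x a \code{\link{PathSet}}
#' @return integer count
#' @export
setGeneric("nPaths", function(x) standardGeneric("nPaths"))

#' @rdname nPaths
#' @export
setMethod("nPaths", "PathSet", function(x) nrow(x@nodes))

#' PWM matrix of a motif or Pwm object
#' @param x a \code{\link{Pwm}} or \code{\link{SpatialMotif}}
#' @return numeric L x W column-stochastic matrix
#' @export
setGeneric("pwmMatrix", function(x) standardGeneric("pwmMatrix"))

#' @rdname pwmMatrix
#' @export
setMethod("pwmMatrix", "Pwm", function(x) x@mat)

#' @rdname pwmMatrix
#' @export
setMethod("pwmMatrix", "SpatialMotif", function(x) x@pwm@mat)

#' Consensus word of a motif
#'
#' Per-column argmax of the PWM, as integer type codes, optionally decoded
#' to type names.
#'
#' @param x a \code{\link{SpatialMotif}}
#' @param typeNames optional character vector mapping codes to names
#' @return integer codes, or character names when \code{typeNames} is given
#' @export
consensusWord <- function(x, typeNames = NULL) {
  stopifnot(is(x, "SpatialMotif"))
  if (is.null(typeNames)) x@consensus else typeNames[x@consensus]
}

#' Member seed table of a motif
#' @param x a \code{\link{SpatialMotif}}
#' @return data.frame of member words with Z, N, P, score columns
#' @export
motifMembers <- function(x) {
  stopifnot(is(x, "SpatialMotif"))
  x@members
}
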