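# Null models: control label configurations by global or kernel-local
# shuffling. Fixed cell types keep their labels and never exchange labels
# with shuffled nodes; erased nodes (label 0) are likewise immutable.

resolveTypes <- function(g, types) {
  if (is.null(types) || length(types) == 0) return(integer(0))
  if (is.character(types)) {
    codes <- match(types, cellTypes(g))
    if (anyNA(codes))
      stop("unknown cell type(s): ",
           paste(types[is.na(codes)], collapse = ", "))
    return(codes)
  }
  as.integer(types)
}

#' Globally shuffle cell-type labels within a section
#'
#' Uniform random permutation of the labels of all non-fixed nodes; nodes
#' whose type is in \code{fixedTypes} (and erased nodes) keep their labels.
#' The label multiset is conserved exactly.
#'
#' @param g a \code{\link{SpatialGraph}}
#' @param fixedTypes cell-type codes or names held fixed
#' @param seed integer seed
#' @return integer label vector (same length as \code{cellLabels(g)})
#' @export
globalShuffle <- function(g, fixedTypes = integer(0), seed = 1L) {
  stopifnot(is(g, "SpatialGraph"))
  fixed <- resolveTypes(g, fixedTypes)
  lab <- cellLabels(g)
  movable <- which(!(lab %in% fixed) & lab != 0L)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  lab[movable] <- lab[sample(movable)]
  lab
}

#' Kernel-local label shuffling
#'
#' Visits the non-fixed nodes once, in a seeded random order; each visited
#' node swaps labels with one uniformly chosen non-fixed node within graph
#' distance \code{K} of it (its "kernel"; the node itself belongs to its
#' kernel, so a draw may be a no-op -- without self-draws a pass of n
#' forced transpositions could only realize permutations of one parity).
#' \code{K = 1} restricts swapping
#' to first neighbors, preserving local cell-type composition; larger K
#' approaches the global shuffle. A node with no eligible partner keeps its
#' label. The label multiset is conserved exactly.
#'
#' @param g a \code{\link{SpatialGraph}}
#' @param K kernel radius in graph hops (>= 1)
#' @param fixedTypes cell-type codes or names held fixed
#' @param seed integer seed
#' @return integer label vector
#' @export
kernelShuffle <- function(g, K, fixedTypes = integer(0), seed = 1L) {
  stopifnot(is(g, "SpatialGraph"))
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("kernel radius K must be >= 1")
  fixed <- resolveTypes(g, fixedTypes)
  lab <- cellLabels(g)
  movable <- !(lab %in% fixed) & lab != 0L
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  visit <- sample(which(movable))
  for (v in visit) {
    ball <- cpp_bfs_ball(g@adj, v, K)
    ball <- c(v, ball[movable[ball]])
    u <- ball[sample.int(length(ball), 1L)]
    tmp <- lab[v]; lab[v] <- lab[u]; lab[u] <- tmp
  }
  lab
}

#' Generate training and scoring control label sets
#'
#' Produces \code{nTrain} control replicates used to train motif
#' significance and \code{nScore} independent replicates used for hold-out
#' scoring, with the same shuffling settings. Each section is shuffled
#' independently, with child seeds derived from the master seed by a fixed
#' rule, so replicates are reproducible and mutually distinct.
#'
#' @param graphs a \code{\link{SpatialGraph}} or named list of them
#' @param method "shuffle" (global) or "kernel" (local)
#' @param K kernel radius in hops (kernel method only)
#' @param fixedTypes cell-type codes or names held fixed
#' @param nTrain number of training replicates (>= 1; default 10)
#' @param nScore number of scoring replicates (>= 1; default 50)
#' @param seed master seed
#' @return list with elements \code{train} and \code{score}; each is a list
#'   of replicates, and each replicate is a named list (section -> labels).
#' @export
buildControls <- function(graphs, method = c("shuffle", "kernel"), K = 1L,
                          fixedTypes = integer(0), nTrain = 10L,
                          nScore = 50L, seed = 1L) {
  method <- match.arg(method)
  graphs <- asGraphList(graphs)
  if (nTrain < 1L) stop("nTrain must be >= 1")
  if (nScore < 1L) stop("nScore must be >= 1")
  oneReplicate <- function(role, i) {
    reps <- lapply(seq_along(graphs), function(si) {
      g <- graphs[[si]]
      s <- deriveSeed(deriveSeed(seed, role, i), "shuffle", si)
      if (method == "shuffle") globalShuffle(g, fixedTypes, s)
      else kernelShuffle(g, K, fixedTypes, s)
    })
    names(reps) <- names(graphs)
    reps
  }
  list(
    train = lapply(seq_len(nTrain), function(i) oneReplicate("train", i)),
    score = lapply(seq_len(nScore), function(i) oneReplicate("score", i))
  )
}
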