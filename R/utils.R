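# Internal helpers: seed chains and word encoding.

# Child seeds are derived from the master seed by a fixed affine rule so that
# per-section / per-replicate work is reproducible and mutually independent
# in the RNG-stream sense. Kept below 2^31 - 1.
deriveSeed <- function(seed, stream, index = 0L) {
  offsets <- c(graph = 11L, sample = 23L, train = 101L, score = 7919L,
               embed = 1409L, labels = 541L, shuffle = 3571L, misc = 89L)
  off <- offsets[[stream]]
  as.integer((as.double(seed) * 48271 + off * 1000003 + index * 2654435) %%
               2147483647)
}

# Words (ordered cell-type tuples) are encoded as base-(L+1) integers stored
# as doubles, big-endian so that numeric order equals lexicographic order of
# the words. Label 0 never occurs in a valid word (erased cells are filtered
# before encoding).
encodeWords <- function(labmat, L) {
  W <- ncol(labmat)
  pow <- (L + 1)^((W - 1):0)
  as.double(labmat %*% pow)
}

decodeWords <- function(ids, W, L) {
  out <- matrix(0L, length(ids), W)
  rem <- ids
  base <- L + 1
  for (j in W:1) {
    out[, j] <- as.integer(rem %% base)
    rem <- (rem - out[, j]) / base
  }
  out
}

formatWord <- function(word, typeNames = NULL) {
  if (is.null(typeNames)) paste(word, collapse = "-")
  else paste(typeNames[word], collapse = "-")
}

# Accept a single SpatialGraph or a list of them; always return a named list.
asGraphList <- function(graphs) {
  if (is(graphs, "SpatialGraph")) {
    out <- list(graphs)
    names(out) <- graphs@section
    return(out)
  }
  stopifnot(is.list(graphs), length(graphs) > 0,
            all(vapply(graphs, is, logical(1), "SpatialGraph")))
  nm <- vapply(graphs, sectionId, character(1))
  names(graphs) <- nm
  graphs
}

logBaseFactor <- function(logBase = 10) {
  logBase <- match.arg(as.character(logBase[1]), c("10", "e"))
  if (logBase == "10") log(10) else 1
}
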