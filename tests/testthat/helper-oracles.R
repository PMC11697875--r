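# Shared fixtures and independent oracles, built in code.

# A triangle with coordinates.
triangleGraph <- function() {
  spatialGraph(cbind(c(0, 2, 1), c(0, 0, 2)), c(1L, 1L, 1L),
               rbind(c(1, 2), c(2, 3), c(1, 3)))
}

# Path graph 1-2-...-n on a line.
lineGraph <- function(n, labels = rep(1L, n), section = "S1") {
  spatialGraph(cbind(seq_len(n), rep(0, n)), labels,
               cbind(seq_len(n - 1), 2:n),
               typeNames = as.character(seq_len(max(labels))),
               section = section)
}

completeGraph <- function(n) {
  ang <- 2 * pi * seq_len(n) / n
  spatialGraph(cbind(cos(ang), sin(ang)), rep(1L, n), t(combn(n, 2)))
}

# Erdos-Renyi random graph with coordinates on a spiral (distinct), L
# available cell types (labels start as 1).
erGraph <- function(n, p, seed, L = 1L) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  if (nrow(e) == 0) e <- pairs[1, , drop = FALSE]
  ang <- 2 * pi * seq_len(n) / n + 0.01 * seq_len(n)
  spatialGraph(cbind(cos(ang) * seq_len(n), sin(ang) * seq_len(n)),
               rep(1L, n), e, typeNames = as.character(seq_len(L)))
}

# Independent oracle for simple-path enumeration: filter all k-tuples of
# vertices (brute force over the full tuple space), keep those whose
# entries are distinct and consecutively adjacent, canonical orientation.
bruteForcePaths <- function(g, k) {
  n <- nCells(g)
  if (k > n) return(matrix(integer(0), 0, k))
  A <- matrix(FALSE, n, n)
  e <- graphEdges(g)
  A[e] <- TRUE
  A[e[, 2:1, drop = FALSE]] <- TRUE
  tup <- as.matrix(expand.grid(rep(list(seq_len(n)), k)))[, k:1, drop = FALSE]
  ok <- rep(TRUE, nrow(tup))
  for (j in seq_len(k - 1)) ok <- ok & A[tup[, c(j, j + 1), drop = FALSE]]
  for (j in seq_len(k - 1)) for (l in (j + 1):k) ok <- ok & tup[, j] != tup[, l]
  ok <- ok & tup[, k] > tup[, 1]
  out <- tup[ok, , drop = FALSE]
  storage.mode(out) <- "integer"
  unname(out)
}

# Canonical string key for a set of paths (order-insensitive comparison).
pathKeys <- function(nodes) {
  if (nrow(nodes) == 0) return(character(0))
  sort(apply(nodes, 1, paste, collapse = "."))
}

# Exact maximum node-disjoint subset of occurrences (exhaustive).
maxDisjointOracle <- function(nodes) {
  m <- nrow(nodes)
  best <- 0L
  for (mask in 0:(2^m - 1)) {
    rows <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(rows) <= best) next
    all_nodes <- as.vector(nodes[rows, , drop = FALSE])
    if (!anyDuplicated(all_nodes)) best <- length(rows)
  }
  best
}

# Negative-binomial survival oracle via pnbinom (distinct code path from
# the pbeta identity used by the implementation).
negbinOracle <- function(y0, w0, y, w, alpha = y0, beta = w0) {
  an <- alpha + sum(y)
  bn <- beta + sum(w)
  pn <- w0 / (bn + w0)
  stats::pnbinom(y0 - 1, size = an, prob = 1 - pn, lower.tail = FALSE,
                 log.p = TRUE) / log(10)
}

# Exhaustive oracle for the delta-median tail probability: enumerate every
# nAM-subset of the nA cells and count subsets with at least n0 (upper) /
# at most nAM - n0 (lower) of their cells among the nH "high" cells.
dmedianOracle <- function(nH, nL, nAM, tail = "upper") {
  nA <- nH + nL
  high <- c(rep(TRUE, nH), rep(FALSE, nL))
  subs <- combn(nA, nAM)
  n0 <- floor(nAM / 2 + 1)
  cnt <- apply(subs, 2, function(s) sum(high[s]))
  if (tail == "upper") mean(cnt >= n0) else mean(cnt <= nAM - n0)
}

# Brute-force all-offset PWM correlation oracle (independent double loop,
# including the column-reversed query).
pwmCorOracle <- function(Q, T_) {
  minOv <- min(ncol(Q), ncol(T_)) - 1L
  best <- -Inf
  for (rev in c(FALSE, TRUE)) {
    qm <- if (rev) Q[, rev(seq_len(ncol(Q))), drop = FALSE] else Q
    for (off in -(ncol(qm) - 1):(ncol(T_) - 1)) {
      cols <- c()
      for (jq in seq_len(ncol(qm))) {
        jt <- jq + off
        if (jt >= 1 && jt <= ncol(T_)) cols <- rbind(cols, c(jq, jt))
      }
      if (is.null(cols) || nrow(cols) < max(1L, minOv)) next
      a <- as.vector(qm[, cols[, 1]])
      b <- as.vector(T_[, cols[, 2]])
      r <- if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
      best <- max(best, r)
    }
  }
  best
}

# Small labeled geometric graph with an embedded word for quick discovery
# tests: returns list(graph, pattern info).
smallEmbeddedGraph <- function(n = 1500, f = 0.05, seed = 42,
                               pattern = "(A/B)CDE") {
  g <- generateRandomGraph(n, L = 12L, seed = seed)
  emb <- embedPatterns(g, pattern, f, seed = seed)
  emb
}
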