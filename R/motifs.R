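# The SMORE core: W-mer extraction, zero-node-in-common (ZNIC) counting,
# negative-binomial seed evaluation, PWM refinement with nested seed
# enrichment, hold-out scoring, motif node erasing, and the discovery loop.

#' Result of a motif discovery run
#'
#' @slot motifs list of \code{\link{SpatialMotif}} in discovery order.
#' @slot graphs the input graphs (named list, one per section) with their
#'   original labels.
#' @slot background background cell-type frequency vector used.
#' @slot config resolved configuration list.
#' @export
setClass("SmoreFit",
  representation(motifs = "list", graphs = "list", background = "numeric",
                 config = "list"))

#' @describeIn SmoreFit-class compact display
#' @param object a \code{SmoreFit}
#' @export
setMethod("show", "SmoreFit", function(object) {
  cat(sprintf("SmoreFit: %d motif(s), %d section(s), W = %d\n",
              length(object@motifs), length(object@graphs),
              object@config$W))
  for (m in object@motifs) show(m)
})

#' Motif list of a fit
#' @param x a \code{\link{SmoreFit}}
#' @return list of \code{SpatialMotif}
#' @export
motifs <- function(x) {
  stopifnot(is(x, "SmoreFit"))
  x@motifs
}

#' Extract W-mers from sampled paths
#'
#' Emits every contiguous W-node window of every path. Apply
#' \code{\link{addReverses}} first so that both orientations of each
#' arrangement are represented.
#'
#' @param ps a \code{\link{PathSet}} (including reverses)
#' @param W motif length (2 <= W <= path length)
#' @return integer matrix of node tuples, one occurrence per row
#' @export
extractWmers <- function(ps, W) {
  stopifnot(is(ps, "PathSet"))
  W <- as.integer(W)
  k <- ps@k
  if (W > k) stop("W = ", W, " exceeds path length k = ", k)
  if (W < 2L) stop("W must be at least 2")
  nd <- ps@nodes
  if (nrow(nd) == 0) return(matrix(integer(0), 0, W))
  wins <- k - W + 1L
  out <- do.call(rbind, lapply(seq_len(wins), function(s)
    nd[, s:(s + W - 1L), drop = FALSE]))
  out
}

#' Zero-node-in-common occurrence count for one word
#'
#' Greedy maximal node-disjoint subset of the occurrences of a single word:
#' occurrences are sorted by (first node, full node tuple) and accepted in
#' order whenever they share no node with a previously accepted occurrence.
#' Counting only node-disjoint instances prevents overlapping occurrences
#' from inflating motif frequencies.
#'
#' @param nodes integer matrix of node tuples, one occurrence per row, all
#'   carrying the same word.
#' @return list with \code{count} (selected subset size) and
#'   \code{selected} (logical row flags)
#' @examples
#' znicCount(rbind(c(1, 2, 3), c(3, 4, 5)))$count  # 1: share node 3
#' znicCount(rbind(c(1, 2, 3), c(4, 5, 6)))$count  # 2: disjoint
#' @export
znicCount <- function(nodes) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "integer"
  if (nrow(nodes) == 0) return(list(count = 0L, selected = logical(0)))
  ord <- do.call(order, lapply(seq_len(ncol(nodes)), function(j) nodes[, j]))
  res <- cpp_znic_count(ord, rep(1L, nrow(nodes)), nodes, 1L,
                        max(nodes))
  list(count = res$counts[1L], selected = res$selected)
}

#' Upper-tail log p-value of the negative-binomial seed test
#'
#' Seed counts per graph are modeled as Poisson with a Gamma-conjugate
#' prior on the rate; the predictive distribution of the primary count
#' given the control counts is negative binomial with shape
#' \code{alpha_n = alpha + sum(y)} and success probability
#' \code{p_n = w0 / (beta + sum(w) + w0)}. The p-value is the upper tail
#' P(Y >= y0), evaluated through the regularized incomplete-beta survival
#' form for numerical stability. By default the prior is \code{alpha = y0},
#' \code{beta = w0}.
#'
#' @param y0 seed ZNIC count in the primary graph.
#' @param w0 total number of ZNIC seeds in the primary graph.
#' @param y control seed ZNIC counts (one per control replicate).
#' @param w control totals (same length as \code{y}).
#' @param alpha,beta Gamma prior shape and rate; default \code{y0}, \code{w0}.
#' @param logBase 10 (default) or "e".
#' @return log p-value (0 when \code{y0 = 0}; always <= 0)
#' @export
negbinLogPvalue <- function(y0, w0, y, w, alpha = y0, beta = w0,
                            logBase = 10) {
  if (length(y) != length(w))
    stop("y and w must have the same length")
  if (any(c(y0, y, w) < 0)) stop("counts must be non-negative")
  if (w0 <= 0) stop("w0 must be positive")
  if (y0 == 0) return(0)
  alphaN <- alpha + sum(y)
  betaN <- beta + sum(w)
  pN <- w0 / (betaN + w0)
  stats::pbeta(pN, y0, alphaN, log.p = TRUE) / logBaseFactor(logBase)
}

# vectorized over cutoffs / words; returns 0 where y0 == 0
negbinLogPvalueVec <- function(y0, w0, ySum, wSum, alpha = y0, beta = w0) {
  alphaN <- alpha + ySum
  pN <- w0 / (beta + wSum + w0)
  out <- numeric(length(y0))
  pos <- y0 > 0
  out[pos] <- stats::pbeta(pN, y0[pos], alphaN[pos], log.p = TRUE) / log(10)
  out
}

#' Initial PWM of a seed word
#'
#' Each column is the seed's one-hot indicator smoothed by the background
#' prior: position j puts mass \code{(1 + rho * b[s_j]) / (1 + rho)} on the
#' seed's type and \code{rho * b[i] / (1 + rho)} on every other type i, so
#' each column sums to one by construction (the prior spreads weight
#' \code{rho} proportionally to the background, consistent with the
#' \code{+ rho * b} term of the maximum-likelihood update). A consequence
#' is that, under the likelihood-ratio score, all words mismatching the
#' seed at the same position score identically, so initial-evaluation
#' p-values break the ties -- which is how degenerate positions are
#' recruited during enrichment. With \code{rho = 0} this is the one-hot
#' indicator matrix of the word.
#'
#' @param word integer vector of type codes (length W)
#' @param background length-L background frequency vector
#' @param rho Dirichlet prior weight (>= 0; default 0.01)
#' @return a \code{\link{Pwm}}
#' @export
initialPwm <- function(word, background, rho = 0.01) {
  if (rho < 0) stop("rho must be non-negative")
  L <- length(background)
  word <- as.integer(word)
  stopifnot(all(word >= 1L & word <= L))
  W <- length(word)
  M <- matrix(rho * background / (1 + rho), L, W)
  M[cbind(word, seq_len(W))] <- (1 + rho * background[word]) / (1 + rho)
  M <- sweep(M, 2, colSums(M), "/")
  new("Pwm", mat = M, background = background, rho = rho)
}

#' Likelihood-ratio score of a word under a PWM
#'
#' \code{sum_j log(M[word_j, j] / b[word_j])}: positive iff the word is
#' more likely under the motif model than under the background. A word
#' containing an erased symbol (0) scores \code{-Inf}.
#'
#' @param pwm a \code{\link{Pwm}}
#' @param word integer vector of type codes (length W; 0 allowed)
#' @return numeric score (natural log)
#' @export
lrScore <- function(pwm, word) {
  stopifnot(is(pwm, "Pwm"))
  W <- ncol(pwm@mat)
  if (length(word) != W) stop("word length must equal PWM width")
  if (any(word == 0L)) return(-Inf)
  sum(log(pwm@mat[cbind(word, seq_len(W))] / pwm@background[word]))
}

#' Maximum-likelihood PWM update from member seeds
#'
#' Weighted sum of the member indicator matrices with weights
#' \code{|P_i| * Z_i / N_i} (more significant seeds weigh more; Z/N is the
#' fraction of a seed's ZNIC sites not claimed by earlier seeds), plus
#' \code{rho * b} in every column, then column normalization.
#'
#' @param words integer matrix of member words (one per row)
#' @param Z incremental ZNIC counts
#' @param N total ZNIC counts (> 0)
#' @param P initial-evaluation log p-values (<= 0)
#' @param background length-L background vector
#' @param rho Dirichlet prior weight
#' @return a \code{\link{Pwm}}
#' @export
updatePwmMle <- function(words, Z, N, P, background, rho = 0.01) {
  words <- as.matrix(words)
  L <- length(background)
  W <- ncol(words)
  wt <- abs(P) * Z / N
  if (all(wt == 0)) stop("degenerate motif: all member weights are zero")
  M <- matrix(rho * background, L, W)
  for (i in which(wt > 0)) {
    M[cbind(words[i, ], seq_len(W))] <-
      M[cbind(words[i, ], seq_len(W))] + wt[i]
  }
  M <- sweep(M, 2, colSums(M), "/")
  new("Pwm", mat = M, background = background, rho = rho)
}

#' Select the enrichment cutoff from a log p-value series
#'
#' Candidate PWM-score cutoffs are ordered from the highest score down;
#' \code{logp[i]} is the significance of pooling the first i seeds. The
#' default mode returns the global minimizer. Differential mode stops at
#' the last cutoff before the p-value first fails to improve, yielding
#' simpler motifs.
#'
#' @param logp numeric vector of log p-values along cutoffs
#' @param differential logical
#' @return integer cutoff index
#' @examples
#' selectCutoff(c(-10, -11, -9, -13))                     # 4 (p = -13)
#' selectCutoff(c(-10, -11, -9, -13), differential = TRUE) # 2 (p = -11)
#' @export
selectCutoff <- function(logp, differential = FALSE) {
  if (!length(logp)) stop("empty p-value series")
  if (!differential) return(which.min(logp))
  i <- 1L
  while (i < length(logp) && logp[i + 1L] < logp[i]) i <- i + 1L
  i
}

#' Hold-out score percentile
#'
#' The reported motif score is the 95th-percentile least significant value
#' across the scoring replicates: replicate log p-values are sorted most
#' significant first and the element at 1-based rank
#' \code{ceiling(q * n)} is returned.
#'
#' @param logp replicate log p-values
#' @param q percentile (default 0.95)
#' @return numeric scalar
#' @export
scorePercentile <- function(logp, q = 0.95) {
  s <- sort(logp)
  s[max(1L, ceiling(q * length(s)))]
}

## ---------------------------------------------------------------------
## Internal discovery machinery
## ---------------------------------------------------------------------

# Pool per-section occurrence matrices into one global-node-indexed matrix,
# sorted deterministically by (section, node tuple).
buildOccurrences <- function(graphs, pathSets, W) {
  offsets <- c(0L, cumsum(vapply(graphs, nCells, integer(1))))
  names(offsets) <- NULL
  nodes <- vector("list", length(graphs))
  secIdx <- vector("list", length(graphs))
  for (si in seq_along(graphs)) {
    wm <- extractWmers(pathSets[[si]], W)
    if (nrow(wm)) {
      ord <- do.call(order, lapply(seq_len(W), function(j) wm[, j]))
      wm <- wm[ord, , drop = FALSE] + offsets[si]
    }
    nodes[[si]] <- wm
    secIdx[[si]] <- rep.int(si, nrow(wm))
  }
  nodes <- do.call(rbind, nodes)
  storage.mode(nodes) <- "integer"
  list(nodes = nodes, section = unlist(secIdx),
       offsets = offsets[-length(offsets)],
       nNodes = offsets[length(graphs) + 1L])
}

globalLabels <- function(labelList) as.integer(unlist(labelList, use.names = FALSE))

# Per-replicate word table: unique words (sorted, so numeric order equals
# lexicographic word order), their ZNIC counts, and the occurrence rows
# grouped by word. Grouping is stored implicitly: `order` lists the valid
# occurrence rows sorted by (word, stored occurrence order), and word i
# occupies order[(starts[i]+1):(starts[i+1])].
buildWordTable <- function(occ, labGlob, W, L) {
  if (nrow(occ$nodes) == 0)
    return(list(uw = numeric(0), counts = integer(0),
                occCounts = integer(0), order = integer(0), starts = 0L,
                total = 0L, mat = matrix(0L, 0, W)))
  tt <- cpp_word_table(labGlob, occ$nodes, L, occ$nNodes)
  tt$starts <- c(0L, cumsum(tt$occCounts))
  tt$mat <- decodeWords(tt$uw, W, L)
  tt
}

# occurrence rows of the words indexed by `idx`, concatenated in that
# order (rows within a word keep the deterministic stored order)
wordRows <- function(tab, idx) {
  sizes <- tab$occCounts[idx]
  tab$order[sequence(sizes) + rep(tab$starts[idx], sizes)]
}

# word scores under a PWM, for a decoded word matrix (rows = words)
wordScoresMat <- function(pwm, mat) {
  if (!nrow(mat)) return(numeric(0))
  S <- log(pwm@mat / pwm@background)
  sc <- S[cbind(mat[, 1L], 1L)]
  for (j in 2:ncol(mat)) sc <- sc + S[cbind(mat[, j], j)]
  sc
}

# Initial seed evaluation: negative-binomial log10 p for every primary
# word against the per-replicate train counts (one y_i, w_i pair per
# control replicate; pooled sums are used only inside enrichment).
evaluateInitialSeeds <- function(tab0, trainTabs) {
  if (!length(tab0$uw))
    return(data.frame(wordId = numeric(0), y0 = integer(0), logP = numeric(0)))
  y0 <- tab0$counts
  ySum <- numeric(length(y0))
  wSum <- 0
  for (tt in trainTabs) {
    mm <- match(tab0$uw, tt$uw)
    yc <- ifelse(is.na(mm), 0L, tt$counts[mm])
    ySum <- ySum + yc
    wSum <- wSum + tt$total
  }
  logP <- negbinLogPvalueVec(y0, tab0$total, ySum, wSum)
  data.frame(wordId = tab0$uw, y0 = y0, logP = logP)
}

# One enrichment iteration: rank positive-score words, walk their
# occurrences with a shared node mask for incremental ZNIC counts, map
# score thresholds into the pooled control counts, and pick the cutoff
# minimizing the negative-binomial log p.
enrichmentIteration <- function(pwm, occ, tab0, trainTabs, pInit,
                                differential = FALSE) {
  # scores are quantized so that exact ties (same mismatch family) are
  # broken by the initial-evaluation p-values, not floating-point noise
  sc0 <- round(wordScoresMat(pwm, tab0$mat), 9)
  cand <- which(sc0 > 0)
  if (!length(cand)) return(NULL)
  ord <- cand[order(-sc0[cand], pInit[cand], tab0$uw[cand])]
  sizes <- tab0$occCounts[ord]
  ordRows <- wordRows(tab0, ord)
  acc <- cpp_masked_walk(ordRows, occ$nodes, occ$nNodes)
  grp <- rep.int(seq_along(ord), sizes)
  Zi <- as.vector(rowsum(as.integer(acc), grp, reorder = FALSE))
  cumY <- cumsum(Zi)
  thr <- sc0[ord]

  # control counts: the same ranked seeds, counted in each replicate with
  # its own shared node mask, pooled over the nTrain replicates
  yCtrl <- numeric(length(ord))
  wCtrl <- 0
  for (tt in trainTabs) {
    wCtrl <- wCtrl + tt$total
    if (!length(tt$uw)) next
    rkT <- match(tt$uw, tab0$uw[ord])
    pres <- which(!is.na(rkT))
    if (!length(pres)) next
    ordT <- pres[order(rkT[pres])]
    rowsT <- wordRows(tt, ordT)
    accT <- cpp_masked_walk(rowsT, occ$nodes, occ$nNodes)
    grpT <- rep.int(seq_along(ordT), tt$occCounts[ordT])
    z <- numeric(length(ord))
    z[rkT[ordT]] <- as.vector(rowsum(as.integer(accT), grpT,
                                     reorder = FALSE))
    yCtrl <- yCtrl + cumsum(z)
  }

  logp <- negbinLogPvalueVec(cumY, tab0$total, yCtrl, wCtrl)
  cut <- selectCutoff(logp, differential)
  sel <- seq_len(cut)
  list(
    wordIdx = ord[sel],               # indices into tab0$uw, ranked
    Z = Zi[sel],
    threshold = thr[cut],
    logP = logp[cut],
    acceptedRows = ordRows[acc & grp <= cut]
  )
}

# Refinement (one iteration per candidate) + nested seed enrichment
# (top nRef candidates, up to nEnrich further iterations while p improves).
refineAndEnrich <- function(candIdx, occ, tab0, trainTabs, pInit, background,
                            rho, nRef, nEnrich, differential) {
  states <- vector("list", length(candIdx))
  pwms <- vector("list", length(candIdx))
  for (i in seq_along(candIdx)) {
    pwm <- initialPwm(tab0$mat[candIdx[i], ], background, rho)
    st <- enrichmentIteration(pwm, occ, tab0, trainTabs, pInit, differential)
    states[[i]] <- st
    pwms[[i]] <- pwm
  }
  keep <- !vapply(states, is.null, logical(1))
  states <- states[keep]; pwms <- pwms[keep]
  if (!length(states)) return(NULL)
  ordC <- order(vapply(states, `[[`, numeric(1), "logP"))
  top <- ordC[seq_len(min(nRef, length(ordC)))]

  for (i in top) {
    st <- states[[i]]; pwm <- pwms[[i]]
    for (iter in seq_len(nEnrich)) {
      newPwm <- tryCatch(
        updatePwmMle(tab0$mat[st$wordIdx, , drop = FALSE], st$Z,
                     tab0$counts[st$wordIdx], pInit[st$wordIdx],
                     background, rho),
        error = function(e) NULL)
      if (is.null(newPwm)) break
      st2 <- enrichmentIteration(newPwm, occ, tab0, trainTabs, pInit,
                                 differential)
      if (is.null(st2) || st2$logP >= st$logP) break
      st <- st2; pwm <- newPwm
    }
    states[[i]] <- st; pwms[[i]] <- pwm
  }
  best <- which.min(vapply(states, `[[`, numeric(1), "logP"))
  c(states[[best]], list(pwm = pwms[[best]]))
}

# Nodes of the ZNIC-selected occurrences of the given words in a table.
# Used for erasing a motif: each labeling (primary or control replicate)
# loses the nodes of its own occurrences of the motif words, so that the
# label pools of primary and controls stay exchangeable across rounds.
selectedWordNodes <- function(tab, occ, wordIds) {
  idx <- match(wordIds, tab$uw)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(integer(0))
  rows <- wordRows(tab, idx)
  rows <- rows[tab$selected[rows]]
  unique(as.vector(occ$nodes[rows, , drop = FALSE]))
}

# Hold-out scoring: the motif's pooled member count in the primary data is
# tested against the ensemble of independent score replicates. One p-value
# is computed per replicate, using the leave-one-out control vector (all
# score replicates except that one), and the 95th-percentile least
# significant log10 p across the replicates is reported. The jackknife
# makes the reported value robust to individual extreme replicates while
# retaining the full ensemble's power. Alongside, the per-replicate nodes
# occupied by the motif words (and their reverses) are collected for the
# erasure step.
scoreMotifState <- function(st, occ, tab0, scoreLabels, W, L,
                            eraseIds = NULL) {
  memberIds <- tab0$uw[st$wordIdx]
  y0 <- sum(tab0$counts[st$wordIdx])
  w0 <- tab0$total
  eraseNodes <- vector("list", length(scoreLabels))
  yr <- numeric(length(scoreLabels))
  wr <- numeric(length(scoreLabels))
  for (i in seq_along(scoreLabels)) {
    tt <- buildWordTable(occ, scoreLabels[[i]], W, L)
    if (!tt$total) { eraseNodes[[i]] <- integer(0); next }
    mm <- match(memberIds, tt$uw)
    yr[i] <- sum(tt$counts[mm[!is.na(mm)]])
    wr[i] <- tt$total
    if (!is.null(eraseIds))
      eraseNodes[[i]] <- selectedWordNodes(tt, occ, eraseIds)
  }
  if (y0 == 0) return(list(logP = 0, eraseNodes = eraseNodes))
  alphaN <- y0 + sum(yr) - yr
  betaN <- w0 + sum(wr) - wr
  pN <- w0 / (betaN + w0)
  logps <- stats::pbeta(pN, y0, alphaN, log.p = TRUE) / log(10)
  list(logP = scorePercentile(logps), eraseNodes = eraseNodes)
}

#' Discover spatial motifs
#'
#' Runs the full discovery loop on one or more labeled neighborhood graphs:
#' sample radial paths with URPEN, convert to W-mers (with reverses), count
#' unique words under the ZNIC model in the primary data and in
#' \code{nTrain} shuffled controls, evaluate seeds with the
#' negative-binomial test, refine the top \code{nEval} seeds by PWM
#' enrichment (top \code{nRef} for up to \code{nEnrich} iterations), score
#' the winning motif against \code{nScore} independent controls, erase its
#' nodes, and repeat until \code{maxMotifs} motifs are found or the scored
#' log10 p-value rises above \code{stopLogP}.
#'
#' @param graphs a \code{\link{SpatialGraph}} or named list of them (one
#'   per section; sections are pooled for counting, shuffled independently
#'   for controls).
#' @param W motif length.
#' @param k sampled path length (>= W; defaults to W).
#' @param level,prob URPEN sampling level / per-depth probabilities
#'   (see \code{\link{samplePaths}}).
#' @param radial restrict sampling to radial paths (default TRUE).
#' @param controlMethod "shuffle" or "kernel".
#' @param kernelK kernel radius for the kernel method.
#' @param fixedTypes cell types held fixed between primary and controls.
#' @param nTrain,nScore number of training / scoring control replicates.
#' @param nEval number of seeds passed to refinement (default 25).
#' @param nRef number of refined candidates enriched further (default 4).
#' @param nEnrich maximum enrichment iterations (default 20).
#' @param rho Dirichlet prior weight for PWMs (default 0.01).
#' @param background optional known background frequency vector (length L);
#'   estimated from the primary label frequencies when NULL.
#' @param differentialP use the differential cutoff rule (simpler motifs).
#' @param maxMotifs maximum number of motifs to report.
#' @param stopLogP stop when a motif's scored log10 p exceeds this
#'   (default -3); the non-significant motif is still reported.
#' @param seed master seed; the full run is deterministic given it.
#' @param verbose print per-motif progress.
#' @return a \code{\link{SmoreFit}}
#' @export
discoverMotifs <- function(graphs, W, k = W, level = 1, prob = NULL,
                           radial = TRUE,
                           radialMode = c("symmetric", "forward", "pairwise"),
                           controlMethod = c("shuffle", "kernel"),
                           kernelK = 1L, fixedTypes = integer(0),
                           nTrain = 10L, nScore = 50L, nEval = 25L,
                           nRef = 4L, nEnrich = 20L, rho = 0.01,
                           background = NULL, differentialP = FALSE,
                           maxMotifs = 10L, stopLogP = -3, seed = 1L,
                           verbose = FALSE) {
  controlMethod <- match.arg(controlMethod)
  radialMode <- match.arg(radialMode)
  graphs <- asGraphList(graphs)
  W <- as.integer(W)
  L <- length(cellTypes(graphs[[1L]]))

  pathSets <- lapply(seq_along(graphs), function(si)
    addReverses(samplePaths(graphs[[si]], k, level = level, prob = prob,
                            radial = radial, radialMode = radialMode,
                            seed = deriveSeed(seed, "sample", si))))
  occ <- buildOccurrences(graphs, pathSets, W)

  primary <- globalLabels(lapply(graphs, cellLabels))
  if (is.null(background)) {
    tabb <- tabulate(primary[primary > 0L], nbins = L)
    background <- tabb / sum(tabb)
  }
  stopifnot(length(background) == L)
  background <- background / sum(background)

  ctl <- buildControls(graphs, method = controlMethod, K = kernelK,
                       fixedTypes = fixedTypes, nTrain = nTrain,
                       nScore = nScore, seed = deriveSeed(seed, "misc"))
  trainLab <- lapply(ctl$train, globalLabels)
  scoreLab <- lapply(ctl$score, globalLabels)

  config <- list(W = W, k = k, level = level, prob = prob, radial = radial,
                 radialMode = radialMode, controlMethod = controlMethod, kernelK = kernelK,
                 fixedTypes = fixedTypes, nTrain = nTrain, nScore = nScore,
                 nEval = nEval, nRef = nRef, nEnrich = nEnrich, rho = rho,
                 differentialP = differentialP, maxMotifs = maxMotifs,
                 stopLogP = stopLogP, seed = seed)

  out <- list()
  if (maxMotifs >= 1L && nrow(occ$nodes) > 0) {
    for (r in seq_len(maxMotifs)) {
      tab0 <- buildWordTable(occ, primary, W, L)
      if (!tab0$total) break
      trainTabs <- lapply(trainLab, buildWordTable, occ = occ, W = W, L = L)
      ev <- evaluateInitialSeeds(tab0, trainTabs)
      ordE <- order(ev$logP, -ev$y0, ev$wordId)
      candIdx <- ordE[seq_len(min(nEval, nrow(ev)))]
      st <- refineAndEnrich(candIdx, occ, tab0, trainTabs, ev$logP,
                            background, rho, nRef, nEnrich, differentialP)
      if (is.null(st)) break
      memberIds <- tab0$uw[st$wordIdx]
      revIds <- encodeWords(tab0$mat[st$wordIdx, W:1, drop = FALSE], L)
      eraseIds <- unique(c(memberIds, revIds))
      sc <- scoreMotifState(st, occ, tab0, scoreLab, W, L,
                            eraseIds = eraseIds)
      logPScore <- sc$logP

      finalPwm <- tryCatch(
        updatePwmMle(tab0$mat[st$wordIdx, , drop = FALSE], st$Z,
                     tab0$counts[st$wordIdx], ev$logP[st$wordIdx],
                     background, rho),
        error = function(e) st$pwm)

      nodesUsed <- sort(selectedWordNodes(tab0, occ, eraseIds))
      secOf <- findInterval(nodesUsed, occ$offsets + 1L)
      occupied <- lapply(seq_along(graphs), function(si)
        nodesUsed[secOf == si] - occ$offsets[si])
      names(occupied) <- names(graphs)

      members <- data.frame(
        word = apply(tab0$mat[st$wordIdx, , drop = FALSE], 1, paste,
                     collapse = "-"),
        wordId = tab0$uw[st$wordIdx],
        Z = st$Z,
        N = tab0$counts[st$wordIdx],
        P = ev$logP[st$wordIdx],
        score = vapply(st$wordIdx, function(i)
          lrScore(st$pwm, tab0$mat[i, ]), numeric(1)),
        stringsAsFactors = FALSE)

      fwdIdx <- match(memberIds, tab0$uw)
      rowsF <- wordRows(tab0, fwdIdx)
      rowsF <- rowsF[tab0$selected[rowsF]]
      accMat <- occ$nodes[rowsF, , drop = FALSE]
      positionNodes <- lapply(seq_len(W), function(j) accMat[, j])

      motif <- new("SpatialMotif", pwm = finalPwm,
                   consensus = as.integer(apply(finalPwm@mat, 2, which.max)),
                   members = members, scoreThreshold = st$threshold,
                   logPTrain = st$logP, logPScore = logPScore,
                   occupiedNodes = occupied, positionNodes = positionNodes,
                   rank = r)
      out[[r]] <- motif
      if (verbose)
        message(sprintf("motif %d: %s  logP(train)=%.2f logP(score)=%.2f",
                        r, paste(motif@consensus, collapse = "-"),
                        st$logP, logPScore))

      # erase the motif: each labeling loses the nodes of its own
      # occurrences of the motif words and their reverses, keeping the
      # primary and control label pools exchangeable in later rounds
      primary[nodesUsed] <- 0L
      for (i in seq_along(trainLab))
        trainLab[[i]][selectedWordNodes(trainTabs[[i]], occ, eraseIds)] <- 0L
      for (i in seq_along(scoreLab))
        scoreLab[[i]][sc$eraseNodes[[i]]] <- 0L

      if (logPScore > stopLogP) break
    }
  }
  new("SmoreFit", motifs = out, graphs = graphs, background = background,
      config = config)
}

#' Per-section motif frequency fingerprint
#'
#' ZNIC counts of each motif's member words in every section (computed on
#' the original, un-erased labels), plus the pairwise Pearson correlation
#' between section rows. Sections with similar cellular architecture have
#' correlated motif-frequency fingerprints and cluster together.
#'
#' @param fit a \code{\link{SmoreFit}} from \code{\link{discoverMotifs}}
#'   run on pooled sections.
#' @return list with \code{counts} (sections x motifs matrix) and
#'   \code{correlation} (sections x sections, unit diagonal). Motifs absent
#'   from every section are excluded from the correlation with a warning.
#' @export
motifFrequencyMatrix <- function(fit) {
  stopifnot(is(fit, "SmoreFit"))
  graphs <- fit@graphs
  if (length(graphs) < 2L)
    stop("motif frequency correlation requires at least two sections")
  W <- fit@config$W
  L <- length(cellTypes(graphs[[1L]]))
  counts <- matrix(0L, length(graphs), length(fit@motifs),
                   dimnames = list(names(graphs),
                                   paste0("motif", seq_along(fit@motifs))))
  for (si in seq_along(graphs)) {
    g <- graphs[[si]]
    ps <- addReverses(samplePaths(g, fit@config$k, level = fit@config$level,
                                  prob = fit@config$prob,
                                  radial = fit@config$radial,
                                  radialMode = fit@config$radialMode,
                                  seed = deriveSeed(fit@config$seed,
                                                    "sample", si)))
    occ <- buildOccurrences(graphs[si], list(ps), W)
    tab <- buildWordTable(occ, cellLabels(g), W, L)
    for (mi in seq_along(fit@motifs)) {
      ids <- fit@motifs[[mi]]@members$wordId
      mm <- match(ids, tab$uw)
      counts[si, mi] <- sum(tab$counts[mm[!is.na(mm)]])
    }
  }
  nz <- colSums(counts) > 0
  if (!all(nz))
    warning(sum(!nz), " motif(s) absent from every section; excluded ",
            "from the correlation")
  cc <- stats::cor(t(counts[, nz, drop = FALSE]))
  diag(cc) <- 1
  list(counts = counts, correlation = cc)
}
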