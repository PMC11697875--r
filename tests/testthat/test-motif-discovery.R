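test_that("W-mer extraction emits every window and respects reverses", {
  g4 <- lineGraph(4, labels = c(1L, 2L, 3L, 1L))
  ps4 <- enumeratePaths(g4, 4)
  expect_equal(nrow(extractWmers(ps4, 4)), 1L)
  g <- lineGraph(5, labels = c(1L, 2L, 3L, 1L, 2L))
  ps5 <- enumeratePaths(g, 5)
  expect_equal(nrow(extractWmers(ps5, 3)), 3L)
  aug <- addReverses(ps5)
  wm <- extractWmers(aug, 5)
  expect_equal(nrow(wm), 2L)
  expect_equal(wm[2, ], rev(wm[1, ]))
  expect_error(extractWmers(ps4, 5), "exceeds")
})

test_that("ZNIC counting takes a maximal greedy node-disjoint subset", {
  expect_equal(znicCount(rbind(c(1, 2, 3), c(3, 4, 5)))$count, 1L)
  expect_equal(znicCount(rbind(c(1, 2, 3), c(4, 5, 6)))$count, 2L)
  set.seed(17)
  for (i in 1:25) {
    m <- sample(4:9, 1)
    occ <- t(replicate(m, sample(12, 3)))
    res <- znicCount(occ)
    exact <- maxDisjointOracle(occ)
    expect_gte(res$count, ceiling(exact / 2))
    expect_lte(res$count, exact)
    # maximality: no unselected occurrence is addable
    usedNodes <- as.vector(occ[res$selected, , drop = FALSE])
    for (r in which(!res$selected))
      expect_true(any(occ[r, ] %in% usedNodes))
  }
})

test_that("negative-binomial log p matches the survival oracle", {
  expect_equal(negbinLogPvalue(0, 100, c(1, 2), c(100, 100)), 0)
  # frozen worked case: y0=3, y=(1,1), w0=w1=w2=100 => alpha_n=5, p_n=0.25
  got <- negbinLogPvalue(3, 100, c(1, 1), c(100, 100))
  expect_equal(got, negbinOracle(3, 100, c(1, 1), c(100, 100)),
               tolerance = 1e-9)
  set.seed(23)
  for (i in 1:100) {
    y0 <- sample(1:50, 1); w0 <- sample(50:5000, 1)
    n <- sample(1:10, 1)
    y <- sample(0:60, n, TRUE); w <- sample(50:5000, n, TRUE)
    expect_equal(negbinLogPvalue(y0, w0, y, w),
                 negbinOracle(y0, w0, y, w), tolerance = 1e-9)
  }
  # monotone: larger y0 never increases the tail probability
  ps <- sapply(1:20, function(y0)
    negbinLogPvalue(y0, 500, c(5, 5), c(500, 500), alpha = 2, beta = 500))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(negbinLogPvalue(3, 0, 1, 10), "w0")
  expect_error(negbinLogPvalue(-1, 10, 1, 10), "non-negative")
})

test_that("initial PWM is the background-smoothed indicator", {
  b <- rep(1 / 3, 3)
  p0 <- initialPwm(c(2, 1), b, rho = 0)
  expect_equal(pwmMatrix(p0), cbind(c(0, 1, 0), c(1, 0, 0)))
  # hand-derived single-column case: match (1 + rho*b)/(1+rho),
  # mismatch rho*b/(1+rho); columns sum to 1 without renormalization
  p1 <- initialPwm(1, b, rho = 0.01)
  expect_equal(pwmMatrix(p1)[1, 1], (1 + 0.01 / 3) / 1.01)
  expect_equal(pwmMatrix(p1)[2, 1], (0.01 / 3) / 1.01)
  expect_equal(colSums(pwmMatrix(p1)), 1)
  p2 <- initialPwm(c(1, 3, 2, 2), c(0.5, 0.3, 0.2), rho = 0.05)
  expect_equal(unname(colSums(pwmMatrix(p2))), rep(1, 4))
  expect_error(initialPwm(1, b, rho = -1), "non-negative")
})

test_that("likelihood-ratio scores follow the closed forms", {
  b <- rep(1 / 4, 4)
  pwm <- initialPwm(c(2, 3, 1), b, rho = 0)
  expect_equal(lrScore(pwm, c(2, 3, 1)), 3 * log(4))
  unif <- new("Pwm", mat = matrix(1 / 4, 4, 3), background = b, rho = 0)
  expect_equal(lrScore(unif, c(1, 4, 2)), 0)
  expect_equal(lrScore(pwm, c(2, 0, 1)), -Inf)
  expect_error(lrScore(pwm, c(1, 2)), "length")
  # consensus scores highest among all words for any PWM
  set.seed(3)
  M <- matrix(rexp(12), 4, 3); M <- sweep(M, 2, colSums(M), "/")
  pw <- new("Pwm", mat = M, background = b, rho = 0)
  cons <- apply(M, 2, which.max)
  words <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  scores <- apply(words, 1, function(w) lrScore(pw, w))
  expect_equal(max(scores), lrScore(pw, cons))
})

test_that("PWM maximum-likelihood update weighs members as |P| Z/N", {
  b <- c(0.5, 0.5)
  one <- updatePwmMle(matrix(c(1, 2), 1), Z = 5, N = 5, P = -3,
                      background = b, rho = 0)
  expect_equal(pwmMatrix(one), cbind(c(1, 0), c(0, 1)))
  # duplicated member words collapse into the same PWM
  two <- updatePwmMle(matrix(c(1, 2, 1, 2), 2, byrow = TRUE),
                      Z = c(5, 5), N = c(5, 5), P = c(-3, -3),
                      background = b, rho = 0)
  expect_equal(pwmMatrix(two), pwmMatrix(one))
  # equal weights on two single-column words average to (0.5, 0.5)
  half <- updatePwmMle(matrix(c(1, 2), 2, 1), Z = c(3, 3), N = c(3, 3),
                       P = c(-2, -2), background = b, rho = 0)
  expect_equal(pwmMatrix(half), matrix(c(0.5, 0.5), 2, 1))
  expect_error(updatePwmMle(matrix(1, 1, 1), Z = 0, N = 3, P = -2,
                            background = b, rho = 0), "degenerate")
  expect_equal(colSums(pwmMatrix(updatePwmMle(
    matrix(c(1, 2, 2, 1), 2, byrow = TRUE), Z = c(2, 1), N = c(3, 2),
    P = c(-4, -1), background = b, rho = 0.01))), rep(1, 2))
})

test_that("enrichment cutoff selection: global minimum vs differential", {
  expect_equal(selectCutoff(c(-10, -11, -9, -13)), 4L)
  expect_equal(selectCutoff(c(-10, -11, -9, -13), differential = TRUE), 2L)
  expect_equal(selectCutoff(c(-5)), 1L)
  expect_equal(selectCutoff(c(-5), differential = TRUE), 1L)
  expect_error(selectCutoff(numeric(0)), "empty")
})

test_that("hold-out score percentile uses rank ceiling(q n)", {
  ps <- sort(-(50:1))          # ascending: most significant first
  expect_equal(scorePercentile(ps), ps[48])
  expect_equal(scorePercentile(rep(-7, 50)), -7)
  expect_equal(scorePercentile(c(-3, -1)), -1)
})

test_that("initial seed evaluation ranks control-absent seeds first", {
  # two seeds with identical primary counts; one also present in controls
  g <- lineGraph(2)
  occ <- list(nodes = matrix(1:2, 1), section = 1L, offsets = 0L,
              nNodes = 2L)
  tab0 <- list(uw = c(10, 20), counts = c(4L, 4L), rows = list(),
               total = 40L, mat = rbind(c(1, 1), c(2, 2)))
  mkTab <- function(uw, counts) list(uw = uw, counts = counts,
                                     rows = list(), total = 40L,
                                     mat = NULL)
  trainTabs <- lapply(1:5, function(i) mkTab(c(20), c(4L)))
  ev <- smore:::evaluateInitialSeeds(tab0, trainTabs)
  expect_lt(ev$logP[ev$wordId == 10], ev$logP[ev$wordId == 20])
})

test_that("discovery recovers a strongly embedded pattern end to end", {
  emb <- smallEmbeddedGraph(n = 1500, f = 0.06, seed = 42)
  fit <- discoverMotifs(emb$graph, W = 4, background = benchmarkBackground(12),
                        nScore = 30, maxMotifs = 2, seed = 42)
  expect_s4_class(fit, "SmoreFit")
  ms <- motifs(fit)
  expect_gte(length(ms), 1L)
  m1 <- ms[[1]]
  expect_gt(bestPwmCorrelation(m1@pwm, emb$pwm), 0.9)
  expect_lt(m1@logPScore, -3)
  # consensus is one of the two embedded variants
  expect_true(paste(consensusWord(m1)[2:4], collapse = "-") == "3-4-5" ||
              paste(rev(consensusWord(m1))[2:4], collapse = "-") == "3-4-5")
  # determinism: identical call, identical motif list
  fit2 <- discoverMotifs(emb$graph, W = 4,
                         background = benchmarkBackground(12),
                         nScore = 30, maxMotifs = 2, seed = 42)
  expect_equal(lapply(motifs(fit2), function(m) m@members),
               lapply(ms, function(m) m@members))
  expect_equal(motifs(fit2)[[1]]@logPScore, m1@logPScore)
  # successive motifs occupy disjoint nodes (erasure)
  if (length(ms) >= 2) {
    expect_length(intersect(ms[[1]]@occupiedNodes[[1]],
                            ms[[2]]@occupiedNodes[[1]]), 0)
  }
  # occupied nodes of the top motif carry the embedded types
  lab <- cellLabels(emb$graph)[m1@occupiedNodes[[1]]]
  expect_true(all(lab %in% c(1:2, 3:5)))
  # position nodes (forward occurrences) are a subset of occupied nodes,
  # which also include the reverse-word occurrences
  posNodes <- unique(unlist(m1@positionNodes))
  expect_true(all(posNodes %in% m1@occupiedNodes[[1]]))
})

test_that("maxMotifs = 0 yields an empty motif list", {
  emb <- smallEmbeddedGraph(n = 600, f = 0, seed = 2)
  fit <- discoverMotifs(emb$graph, W = 3, nTrain = 2, nScore = 2,
                        maxMotifs = 0, seed = 1)
  expect_length(motifs(fit), 0)
})

test_that("motif frequency fingerprints cluster sections by architecture", {
  mkSec <- function(seed, f, sec) {
    emb <- smallEmbeddedGraph(n = 900, f = f, seed = seed)
    g <- emb$graph
    g@section <- sec
    g
  }
  gl <- list(s1 = mkSec(1, 0.06, "s1"), s2 = mkSec(2, 0.06, "s2"),
             s3 = mkSec(3, 0, "s3"))
  fit <- discoverMotifs(gl, W = 4, background = benchmarkBackground(12),
                        nTrain = 5, nScore = 10, maxMotifs = 2, seed = 4)
  expect_gte(length(motifs(fit)), 1L)
  fm <- motifFrequencyMatrix(fit)
  expect_equal(dim(fm$counts), c(3L, length(motifs(fit))))
  expect_equal(diag(fm$correlation), rep(1, 3), ignore_attr = TRUE)
  expect_equal(fm$correlation, t(fm$correlation))
  # the two embedded sections carry the top motif, the background one not
  expect_true(all(fm$counts[1:2, 1] > fm$counts[3, 1]))
  # single section: correlation undefined
  fit1 <- discoverMotifs(gl$s1, W = 4, background = benchmarkBackground(12),
                         nTrain = 2, nScore = 5, maxMotifs = 1, seed = 4)
  expect_error(motifFrequencyMatrix(fit1), "two sections")
})
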