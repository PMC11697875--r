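test_that("benchmark background is near-uniform with < 2x spread", {
  b <- benchmarkBackground(12)
  expect_equal(sum(b), 1)
  expect_lt(max(b) / min(b), 2)
  expect_equal(max(b) / min(b), 12^(1 / 4))
})

test_that("random Delaunay graphs satisfy planarity and reproducibility", {
  g4 <- generateRandomGraph(4, seed = 2)
  expect_true(nrow(graphEdges(g4)) %in% 5:6)
  g <- generateRandomGraph(2000, seed = 5)
  ne <- nrow(graphEdges(g))
  expect_lte(ne, 3 * 2000 - 6)
  expect_gte(ne, 3 * 2000 - 6 - 150)   # hull slack
  g2 <- generateRandomGraph(2000, seed = 5)
  expect_identical(graphEdges(g), graphEdges(g2))
  g3 <- generateRandomGraph(2000, seed = 6)
  expect_false(identical(graphEdges(g), graphEdges(g3)))
})

test_that("background label assignment follows the frequency vector", {
  g <- generateRandomGraph(4000, seed = 1)
  lab <- assignBackgroundLabels(g, rep(1, 12), seed = 2)
  freq <- tabulate(lab, 12) / 4000
  expect_true(all(abs(freq - 1 / 12) < 4 * sqrt((1 / 12) * (11 / 12) / 4000)))
  labF <- assignBackgroundLabels(g, benchmarkBackground(12), seed = 3)
  expect_gt(sum(labF == 1), sum(labF == 12))
})

test_that("pattern parsing handles the (A/B)CDE form", {
  p <- parsePattern("(A/B)CDE")
  expect_equal(p$W, 4L)
  expect_equal(p$varPos, 1L)
  expect_equal(p$alts, c(1L, 2L))
  expect_equal(p$fixed, c(NA, 3L, 4L, 5L))
  p2 <- parsePattern("AC(D/F)E")
  expect_equal(p2$varPos, 3L)
  expect_equal(p2$alts, c(4L, 6L))
  expect_error(parsePattern("ABCD"), "variable position")
  expect_error(parsePattern("(A/B)(C/D)"), "exactly one")
})

test_that("embedding arithmetic and contracts hold", {
  g <- generateRandomGraph(3000, seed = 4)
  # default budget: floor(f n / W) patterns per variable-position variant
  emb <- embedPatterns(g, "(A/B)CDE", 0.02, seed = 4)
  expect_equal(emb$nEmbedded, 2L * floor(0.02 * 3000 / 4))
  expect_equal(emb$nNodesUsed, emb$nEmbedded * 4L)
  # occurrences are node-disjoint and radial
  occ <- emb$occurrences
  expect_false(anyDuplicated(as.vector(occ)) > 0)
  co <- spatialCoords(emb$graph)
  expect_true(all(apply(occ, 1, isRadial, coords = co)))
  # embedded labels match the pattern with variable first position
  lab <- cellLabels(emb$graph)
  words <- matrix(lab[occ], nrow(occ))
  expect_true(all(words[, 1] %in% 1:2))
  expect_equal(sum(words[, 1] == 1L), sum(words[, 1] == 2L))
  expect_true(all(words[, 2] == 3 & words[, 3] == 4 & words[, 4] == 5))
  # f = 0: pure background
  emb0 <- embedPatterns(g, "(A/B)CDE", 0, seed = 4)
  expect_equal(emb0$nEmbedded, 0L)
  # total budget: floor(f n / W) patterns overall, exactly f n nodes
  embT <- embedPatterns(g, "(A/B)CDE", 0.02, seed = 4, budget = "total")
  expect_equal(embT$nEmbedded, 15L)
  expect_equal(embT$nNodesUsed, 60L)
  # infeasible request reports the achievable maximum
  expect_error(embedPatterns(g, "(A/B)CDE", 0.9, seed = 4), "available")
})

test_that("ground-truth PWM reflects the realized degenerate position", {
  g <- generateRandomGraph(4000, seed = 9)
  emb <- embedPatterns(g, "(A/B)CDE", 0.03, seed = 9)
  M <- pwmMatrix(emb$pwm)
  expect_equal(colSums(M), rep(1, 4), ignore_attr = TRUE)
  expect_gt(M[1, 1] + M[2, 1], 0.95)
  expect_gt(min(M[1, 1], M[2, 1]), 0.2)
  expect_gt(M[3, 2], 0.95)
})

test_that("best PWM correlation matches the brute-force offset oracle", {
  set.seed(19)
  mk <- function(L, W) {
    M <- matrix(rexp(L * W), L, W)
    sweep(M, 2, colSums(M), "/")
  }
  A <- mk(12, 4)
  expect_equal(bestPwmCorrelation(A, A), 1.0)
  B <- A
  B[, 2] <- 0; B[7, 2] <- 1
  expect_lt(bestPwmCorrelation(B, A), 1.0)
  for (i in 1:50) {
    Q <- mk(12, sample(3:5, 1)); T_ <- mk(12, sample(3:5, 1))
    expect_equal(bestPwmCorrelation(Q, T_), pwmCorOracle(Q, T_),
                 tolerance = 1e-12)
    # symmetry and joint row-permutation invariance
    expect_equal(bestPwmCorrelation(Q, T_), bestPwmCorrelation(T_, Q),
                 tolerance = 1e-12)
    pr <- sample(12)
    expect_equal(bestPwmCorrelation(Q[pr, ], T_[pr, ]),
                 bestPwmCorrelation(Q, T_), tolerance = 1e-12)
  }
})

test_that("TPR/FPR arithmetic follows the confusion-matrix definitions", {
  r <- computeTprFpr(pcc = rep(0.99, 4), logp = rep(-20, 4),
                     logpThreshold = -10)
  expect_equal(r$TPR, 1)
  expect_true(is.na(r$FPR))
  r2 <- computeTprFpr(pcc = rep(0.1, 4), logp = rep(-20, 4),
                      logpThreshold = -10)
  expect_equal(r2$FPR, 1)
  expect_true(is.na(r2$TPR))
  # hand tally of 8 (pcc, logp) pairs at thresholds 0.95 / -10:
  pcc <-  c(0.99, 0.97, 0.80, 0.99, 0.50, 0.96, 0.10, 0.94)
  logp <- c(-15,  -5,   -12,  -11,  -1,   -9,   -20,  -10)
  # TP: 1,4 (hi & sig)  FN: 2,6 (hi & not)  FP: 3,7,8  TN: 5
  r3 <- computeTprFpr(pcc, logp, logpThreshold = -10)
  expect_equal(r3$TPR, 2 / 4)
  expect_equal(r3$FPR, 3 / 4)
})

test_that("success rate counts runs with a significant accurate motif", {
  runs <- list(data.frame(pcc = c(0.99, 0.2), logp = c(-15, -12)),
               data.frame(pcc = c(0.99, 0.3), logp = c(-5, -2)),
               data.frame(pcc = c(0.5, 0.98), logp = c(-20, -11)))
  expect_equal(successRate(runs, logpThreshold = -10), 2 / 3)
  expect_equal(successRate(runs, logpThreshold = -30), 0)
})
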