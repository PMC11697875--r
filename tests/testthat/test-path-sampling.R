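test_that("path enumeration matches closed-form counts on canonical graphs", {
  expect_equal(pathNodes(enumeratePaths(lineGraph(3), 3)),
               matrix(1:3, 1, byrow = TRUE))
  expect_equal(nPaths(enumeratePaths(triangleGraph(), 3)), 3L)
  expect_equal(nPaths(enumeratePaths(completeGraph(4), 3)), 12L)
  expect_error(enumeratePaths(lineGraph(3), 1), "at least 2")
  expect_equal(nPaths(enumeratePaths(lineGraph(3), 4)), 0L)
})

test_that("enumeration equals the brute-force tuple oracle on random graphs", {
  for (i in 1:12) {
    n <- sample(5:12, 1)
    g <- erGraph(n, runif(1, 0.25, 0.6), seed = 100 + i)
    for (k in 2:5) {
      got <- pathKeys(pathNodes(enumeratePaths(g, k)))
      want <- pathKeys(bruteForcePaths(g, k))
      expect_identical(got, want)
    }
  }
})

test_that("no duplicate paths and canonical orientation hold", {
  g <- erGraph(10, 0.5, seed = 3)
  nd <- pathNodes(enumeratePaths(g, 4))
  expect_false(anyDuplicated(nd) > 0)
  expect_true(all(nd[, 4] > nd[, 1]))
})

test_that("radial condition is the symmetric two-endpoint criterion", {
  co <- cbind(c(0, 1, 2, 3), c(0, 0, 0, 0))
  expect_true(isRadial(c(1, 2, 3, 4), co))
  co2 <- cbind(c(0, 2, 1), c(0, 0, 0.1))
  expect_false(isRadial(c(1, 2, 3), co2))         # doubles back
  expect_true(isRadial(c(1, 2), co2))             # 2-node path vacuous
  expect_error(isRadial(c(1), co2), "at least 2")
  # ties fail (strict monotonicity): second and third node equidistant
  # from the first
  co3 <- cbind(c(0, 1, 0), c(0, 0, 1))
  expect_false(isRadial(c(1, 2, 3), co3))
  # a path is radial iff its reverse is
  set.seed(11)
  co4 <- matrix(runif(24), 12, 2)
  for (i in 1:40) {
    nd <- sample(12, 4)
    expect_equal(isRadial(nd, co4), isRadial(rev(nd), co4))
  }
})

test_that("radial enumeration equals post-hoc filtering of all paths", {
  set.seed(21)
  cells <- data.frame(x = runif(60), y = runif(60), cell_type = 1)
  g <- buildGraph(cells, method = "delaunay")[[1]]
  all4 <- enumeratePaths(g, 4, radial = FALSE)
  rad4 <- enumeratePaths(g, 4, radial = TRUE)
  keep <- apply(pathNodes(all4), 1, isRadial, coords = spatialCoords(g))
  expect_identical(pathKeys(pathNodes(rad4)),
                   pathKeys(pathNodes(all4)[keep, , drop = FALSE]))
  # forward-only variant accepts a superset of the symmetric criterion
  fwd4 <- enumeratePaths(g, 4, radial = TRUE, radialMode = "forward")
  expect_true(all(pathKeys(pathNodes(rad4)) %in%
                  pathKeys(pathNodes(fwd4))))
})

test_that("URPEN with unit probabilities reproduces exhaustive enumeration", {
  g <- erGraph(10, 0.5, seed = 5)
  full <- enumeratePaths(g, 4)
  samp <- samplePaths(g, 4, level = 1, radial = FALSE, seed = 1)
  expect_identical(pathKeys(pathNodes(full)), pathKeys(pathNodes(samp)))
  empty <- samplePaths(g, 4, prob = c(1, 1, 1, 0), radial = FALSE, seed = 1)
  expect_equal(nPaths(empty), 0L)
  expect_error(samplePaths(g, 4, prob = c(1, 1, 1, 1.2)), "\\[0, 1\\]")
  expect_error(samplePaths(g, 4, prob = c(1, 1)), "length k")
})

test_that("URPEN samples each path uniformly at the requested level", {
  set.seed(31)
  cells <- data.frame(x = runif(60), y = runif(60), cell_type = 1)
  g <- buildGraph(cells, method = "delaunay")[[1]]
  full <- pathNodes(enumeratePaths(g, 3, radial = TRUE))
  keys <- pathKeys(full)
  R <- 400; lev <- 0.5
  counts <- setNames(numeric(length(keys)), keys)
  for (r in seq_len(R)) {
    s <- samplePaths(g, 3, level = lev, radial = TRUE, seed = 5000 + r)
    kk <- pathKeys(pathNodes(s))
    counts[kk] <- counts[kk] + 1
  }
  expect_equal(mean(counts), R * lev, tolerance = 0.05)
  # aggregate binomial goodness of fit across paths
  chi <- sum((counts - R * lev)^2) / (R * lev * (1 - lev))
  pval <- pchisq(chi, df = length(counts), lower.tail = FALSE)
  expect_gt(pval, 0.001)
  # sampling quality (<= 20% count error among paths with >= 5 counts)
  # reaches 1 at complete sampling
  exact <- samplePaths(g, 3, level = 1, radial = TRUE, seed = 1)
  expect_identical(pathKeys(pathNodes(exact)), keys)
})

test_that("reverse augmentation exactly doubles a canonical path set", {
  ps <- enumeratePaths(triangleGraph(), 3)
  aug <- addReverses(ps)
  expect_equal(nPaths(aug), 2L * nPaths(ps))
  nd <- pathNodes(aug)
  expect_equal(nd[4:6, ], nd[1:3, 3:1])
  empty <- samplePaths(triangleGraph(), 3, prob = c(0, 1, 1), seed = 1)
  expect_equal(nPaths(addReverses(empty)), 0L)
  # words of reverses are reversed
  g <- lineGraph(4, labels = c(1L, 2L, 3L, 2L))
  aug2 <- addReverses(enumeratePaths(g, 4))
  w <- pathWords(aug2, g)
  expect_equal(w[2, ], rev(w[1, ]))
})

test_that("sampling is deterministic given the master seed", {
  g <- erGraph(12, 0.4, seed = 9)
  a <- samplePaths(g, 4, level = 0.3, radial = FALSE, seed = 77)
  b <- samplePaths(g, 4, level = 0.3, radial = FALSE, seed = 77)
  expect_identical(pathNodes(a), pathNodes(b))
  c <- samplePaths(g, 4, level = 0.3, radial = FALSE, seed = 78)
  expect_false(identical(pathNodes(a), pathNodes(c)))
})
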