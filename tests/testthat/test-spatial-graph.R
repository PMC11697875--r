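test_that("delaunay graph of a single triangle is the triangle", {
  cells <- data.frame(x = c(0, 2, 1), y = c(0, 0, 2),
                      cell_type = c("A", "B", "A"))
  g <- buildGraph(cells, method = "delaunay")[[1]]
  expect_s4_class(g, "SpatialGraph")
  expect_equal(nCells(g), 3L)
  expect_equal(graphEdges(g), rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_equal(cellTypes(g), c("A", "B"))
  expect_equal(cellLabels(g), c(1L, 2L, 1L))
})

test_that("delaunay of four points matches the hand-verified triangulation", {
  # points (0,0),(4,0),(2,1),(2,5): the circumcircle conditions were
  # checked analytically (centers (2,-1.5), (-0.25,3) and mirror; the
  # fourth point lies outside each), giving triangles 1-2-3, 1-3-4, 2-3-4
  cells <- data.frame(x = c(0, 4, 2, 2), y = c(0, 0, 1, 5), cell_type = 1)
  g <- buildGraph(cells, method = "delaunay")[[1]]
  expect_equal(graphEdges(g),
               rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                     c(2L, 3L), c(2L, 4L), c(3L, 4L)))
})

test_that("knn graph takes the undirected union of nearest neighbors", {
  cells <- data.frame(x = c(0, 1, 2), y = c(0, 1, 2), cell_type = 1)
  g <- buildGraph(cells, method = "knn", param = 1)[[1]]
  expect_equal(graphEdges(g), rbind(c(1L, 2L), c(2L, 3L)))
  # union symmetrization only adds edges: degree >= K
  set.seed(5)
  cells2 <- data.frame(x = runif(40), y = runif(40), cell_type = 1)
  g2 <- buildGraph(cells2, method = "knn", param = 3)[[1]]
  deg <- tabulate(graphEdges(g2), nbins = 40)
  expect_true(all(deg >= 3))
})

test_that("epsilon graph connects exactly the pairs within the radius", {
  cells <- data.frame(x = c(0, 1, 3), y = 0, cell_type = 1)
  g <- buildGraph(cells, method = "epsilon", param = 1.5)[[1]]
  expect_equal(graphEdges(g), rbind(c(1L, 2L)))
})

test_that("graph construction is label-agnostic and validates input", {
  set.seed(7)
  cells <- data.frame(x = runif(30), y = runif(30),
                      cell_type = sample(3, 30, TRUE))
  cells2 <- cells
  cells2$cell_type <- sample(cells$cell_type)
  g1 <- buildGraph(cells, method = "delaunay")[[1]]
  g2 <- buildGraph(cells2, method = "delaunay")[[1]]
  expect_equal(graphEdges(g1), graphEdges(g2))
  # planarity bound for 2D delaunay
  expect_lte(nrow(graphEdges(g1)), 3 * 30 - 6)

  expect_error(buildGraph(cells[, c("x", "y")]), "cell_type")
  expect_error(buildGraph(cells, method = "knn"), "K >= 1")
  expect_error(buildGraph(cells, method = "epsilon"), "radius > 0")
  collin <- data.frame(x = 0:4, y = 2 * (0:4), cell_type = 1,
                       section = "s7")
  expect_error(buildGraph(collin, method = "delaunay"), "s7")
})

test_that("duplicate coordinates error unless deterministic jitter opted in", {
  cells <- data.frame(x = c(0, 0, 1, 2, 1), y = c(0, 0, 1, 0, 2),
                      cell_type = 1, section = "dup")
  expect_error(buildGraph(cells, method = "delaunay"), "dup")
  g1 <- buildGraph(cells, method = "delaunay", jitterDuplicates = TRUE,
                   seed = 9)[[1]]
  g2 <- buildGraph(cells, method = "delaunay", jitterDuplicates = TRUE,
                   seed = 9)[[1]]
  expect_equal(spatialCoords(g1), spatialCoords(g2))
  expect_equal(nCells(g1), 5L)
})

test_that("sections become separate graphs", {
  cells <- data.frame(x = c(0, 2, 1, 0, 2, 1), y = c(0, 0, 2, 0, 0, 2),
                      cell_type = 1,
                      section = rep(c("a", "b"), each = 3))
  gl <- buildGraph(cells, method = "delaunay")
  expect_named(gl, c("a", "b"))
  expect_equal(sectionId(gl$b), "b")
  expect_equal(nCells(gl$a), 3L)
})

test_that("forward neighborhood excludes the given set", {
  g <- triangleGraph()
  expect_equal(forwardNeighborhood(g, 1), c(2L, 3L))
  expect_equal(forwardNeighborhood(g, 1, 2), 3L)
  expect_equal(forwardNeighborhood(g, 1, c(2, 3)), integer(0))
  expect_error(forwardNeighborhood(g, 9), "not in the graph")
})

test_that("graph writer emits 0-based node and edge tables", {
  g <- triangleGraph()
  nf <- tempfile(fileext = ".tsv"); ef <- tempfile(fileext = ".tsv")
  writeGraph(g, nf, ef)
  nodes <- read.delim(nf)
  edges <- read.delim(ef)
  expect_equal(nodes$index, 0:2)
  expect_equal(edges$v1, c(0L, 0L, 1L))
  expect_equal(edges$v2, c(1L, 2L, 2L))
})

test_that("delaunay rejects 3D coordinates with a pointer to knn/epsilon", {
  cells <- data.frame(x = runif(10), y = runif(10), z = runif(10),
                      cell_type = 1)
  expect_error(buildGraph(cells, method = "delaunay"), "knn")
  g <- buildGraph(cells, method = "knn", param = 2)[[1]]
  expect_equal(ncol(spatialCoords(g)), 3L)
})
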