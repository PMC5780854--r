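d <- 0.85
cfg <- walkConfig()

test_that("transition matrix rows are damped, weight-normalized, boundary-aware", {
  # path with both ends boundary: the single transient row is empty
  M <- transitionMatrix(pathABC(), boundary = c("A", "C"))
  expect_equal(dim(M), c(1L, 1L))
  expect_equal(as.numeric(M), 0)

  # star: uniform split of the damping mass
  star <- symMatrix(c("c", "s1", "s2", "s3", "s4"),
                    cbind(rep("c", 4), paste0("s", 1:4), rep(1, 4)))
  M <- transitionMatrix(star)
  expect_equal(as.numeric(M["c", paste0("s", 1:4)]), rep(d / 4, 4))
  expect_lte(max(Matrix::rowSums(M)), d + 1e-12)

  # weighted triangle: rows match hand normalization
  tri <- symMatrix(c("x", "y", "z"),
                   rbind(c("x", "y", 1), c("y", "z", 2), c("x", "z", 3)))
  M <- transitionMatrix(tri)
  expect_equal(as.numeric(M["x", c("y", "z")]), d * c(1, 3) / 4)
  expect_equal(as.numeric(M["y", c("x", "z")]), d * c(1, 2) / 3)
  expect_equal(as.numeric(M["z", c("x", "y")]), d * c(3, 2) / 5)
})

test_that("path-graph visits, absorption and channel match the closed forms", {
  W <- pathABC()
  v <- emittingVisits(W, "A", "C")
  expect_equal(v[["B"]], d / (1 - d^2 / 2), tolerance = 1e-12)
  expect_equal(v[["A"]], 1 / (1 - d^2 / 2), tolerance = 1e-12)

  a <- absorbingProbability(W, "C")
  expect_equal(a[["B"]], (d / 2) / (1 - d^2 / 2), tolerance = 1e-12)
  expect_equal(a[["A"]], d * (d / 2) / (1 - d^2 / 2), tolerance = 1e-12)

  h <- channelVisits(W, "A", "C")
  expect_equal(h[["B"]], 1 / (1 - d^2 / 2), tolerance = 1e-12)
})

test_that("damping limits and unreachable nodes behave as expected", {
  # nearly-zero damping: nothing two hops away is visited
  W <- pathABC()
  v <- emittingVisits(W, "A", config = walkConfig(damping = 1e-4))
  expect_lt(v[["C"]], 1e-7)

  # a node adjacent only to the sink absorbs with probability = damping
  a <- absorbingProbability(symMatrix(c("u", "s"), cbind("u", "s", 1)), "s")
  expect_equal(a[["u"]], d)

  # disconnected node: zero visits, zero absorption, empty channel
  nodes <- c("A", "B", "C", "lone")
  W2 <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  W2[1:3, 1:3] <- pathABC()
  expect_equal(emittingVisits(W2, "A", "C")[["lone"]], 0)
  expect_equal(absorbingProbability(W2, "C")[["lone"]], 0)
  expect_warning(h <- channelVisits(W2, "lone", "C"), "unreachable")
  expect_length(h, 0L)
})

test_that("expected visits are monotone non-decreasing in damping", {
  for (seed in c(101, 102)) {
    W <- randomFixtureGraph(seed, nNodes = 8L)
    sink <- "n08"
    prev <- NULL
    for (dd in c(0.3, 0.6, 0.85, 0.95)) {
      v <- emittingVisits(W, "n01", sink, walkConfig(damping = dd))
      if (!is.null(prev)) expect_true(all(v >= prev - 1e-12))
      prev <- v
    }
  }
})

test_that("absorbed plus dissipated probability is unity", {
  for (seed in 201:204) {
    W <- randomFixtureGraph(seed)
    nodes <- rownames(W)
    fc <- flowConservation(W, nodes[1L], nodes[length(nodes)])
    expect_equal(fc$absorbed + fc$dissipated, 1, tolerance = 1e-9)
  }
  # also with no sink at all: everything dissipates
  fc <- flowConservation(pathABC(), "A")
  expect_equal(fc$absorbed, 0)
  expect_equal(fc$dissipated, 1, tolerance = 1e-9)
})

test_that("emitting and channel visits match the Monte-Carlo walker", {
  W <- randomFixtureGraph(301, nNodes = 8L)
  nodes <- rownames(W)
  src <- nodes[1L]; snk <- nodes[8L]

  em <- mcEmitting(W, d, src, snk, nWalks = 1e5, seed = 77)
  v <- emittingVisits(W, src, snk)
  expect_within_3se(v, em$mean[names(v)], em$se[names(v)], "emitting")

  ch <- mcChannel(W, d, src, snk, nWalks = 1e5, seed = 78)
  h <- channelVisits(W, src, snk)
  expect_within_3se(h, ch$mean[names(h)], ch$se[names(h)], "channel")

  ab <- mcAbsorbing(W, d, nodes[3L], snk, nWalks = 1e5, seed = 79)
  a <- absorbingProbability(W, snk)
  expect_lt(abs(a[[nodes[3L]]] - ab$p), 3 * ab$se + 1e-9)
})

test_that("term vectors respect reachability, symmetry and the MC oracle", {
  # a term whose only gene has no interactions: one nonzero entry
  lonely <- new("WTGGN", termNodes = "t1", geneNodes = c("g1", "g2"),
                tgEdges = data.frame(term = "t1", gene = "g1", weight = 0.5,
                                     stringsAsFactors = FALSE),
                ggEdges = data.frame(gene1 = character(),
                                     gene2 = character(),
                                     weight = numeric(),
                                     stringsAsFactors = FALSE),
                termWeights = c(t1 = 1), dropped = character())
  tv <- termVector(lonely, "t1")
  w <- visitWeights(tv)
  expect_gt(w[["g1"]], 0)
  expect_equal(w[["g2"]], 0)

  # two terms with identical edge weights onto an automorphic gene pair
  twin <- new("WTGGN", termNodes = c("t1", "t2"),
              geneNodes = c("g1", "g2"),
              tgEdges = data.frame(term = c("t1", "t2"),
                                   gene = c("g1", "g2"),
                                   weight = c(0.5, 0.5),
                                   stringsAsFactors = FALSE),
              ggEdges = data.frame(gene1 = "g1", gene2 = "g2", weight = 0.3,
                                   stringsAsFactors = FALSE),
              termWeights = c(t1 = 1, t2 = 1), dropped = character())
  w1 <- visitWeights(termVector(twin, "t1"))
  w2 <- visitWeights(termVector(twin, "t2"))
  expect_equal(unname(w1[c("g1", "g2")]), unname(w2[c("g2", "g1")]))

  # 6-node toy network against the conditioned Monte-Carlo walker on the
  # hand-built split graph
  net <- toyWTGGN()
  tv1 <- visitWeights(termVector(net, "t1"))
  Wsplit <- splitWalkMatrix(net, "t1")
  mc <- mcChannel(Wsplit, d, "SRC", "t1", nWalks = 1e5, seed = 42)
  expect_within_3se(tv1, mc$mean[names(tv1)], mc$se[names(tv1)],
                    "term vector")

  expect_error(termVector(net, "nope"), "not a term node")
})

test_that("solver certifies residuals and rejects bad configs", {
  expect_error(walkConfig(damping = 1), "damping")
  expect_error(walkConfig(damping = 0), "damping")
  expect_error(emittingVisits(pathABC(), "C", sinks = "C"), "transient")
  expect_error(absorbingProbability(pathABC(), character()), "sink")
})
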