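# Graph thresholding and the four weighted node metrics.

test_that("thresholding keeps surviving weights and zeroes the diagonal", {
  set.seed(20)
  W <- matrix(runif(49), 7); W <- (W + t(W)) / 2; diag(W) <- 1
  out0 <- applyThreshold(W, 0)
  expect_identical(diag(out0), rep(0, 7))
  expect_equal(out0[upper.tri(out0)], W[upper.tri(W)])
  # cutoff above the maximum empties the graph
  expect_true(all(applyThreshold(W, max(W) + 1) == 0))
  # survivor count matches a counting oracle
  thr <- 0.5
  outT <- applyThreshold(W, thr)
  offdiag <- W[upper.tri(W)]
  expect_identical(sum(outT[upper.tri(outT)] > 0),
                   sum(offdiag >= thr))
})

test_that("cost-efficiency threshold matches exhaustive search", {
  W <- twoCliqueBridge(0.9, 0.1)
  diag(W) <- 1
  grid <- seq(0.1, 0.9, by = 0.05)
  spec <- costEfficiencyThreshold(W, grid)
  # exhaustive oracle over the same candidate costs
  npairs <- 28
  ws <- sort(W[upper.tri(W)], decreasing = TRUE)
  best <- -Inf; bestCost <- NA
  for (k in grid) {
    thr <- ws[max(1, round(k * npairs))]
    adj <- (W >= thr & W > 0) * 1; diag(adj) <- 0
    eg <- bruteGlobalEfficiency(adj)
    if (eg - k > best + 1e-12) { best <- eg - k; bestCost <- k }
  }
  expect_equal(spec$costEfficiency, best)
  expect_identical(spec$table$cost[which.max(spec$table$costEfficiency)],
                   bestCost)
  expect_true(spec$costAtThreshold > 0 && spec$costAtThreshold <= 1)
})

test_that("star graph maximizes cost-efficiency at minimal spanning cost", {
  # K_{1,4}: all information flows through the center; adding no edge can
  # beat keeping exactly the 4 spokes
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- 0.8
  diag(W) <- 1
  grid <- seq(0.1, 0.9, by = 0.1)
  spec <- costEfficiencyThreshold(W, grid)
  # 4 spokes of 10 possible edges = cost 0.4; the C-E argmax keeps them all
  expect_equal(spec$costAtThreshold, 0.4)
})

test_that("node strength is the row sum of weights", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.25
  expect_equal(nodeStrength(W), c(0.75, 0.5, 0.25))
  expect_identical(nodeStrength(matrix(0, 4, 4)), rep(0, 4))
})

test_that("clustering coefficient handles canonical graphs", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  expect_equal(clusteringCoefficient(tri), rep(1, 3))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_identical(clusteringCoefficient(star), rep(0, 4))

  # weighted triangle (1, 1, 0.125): node opposite the weak edge sees the
  # geometric mean (1 * 1 * 0.125)^(1/3) = 0.5
  wt <- matrix(0, 3, 3)
  wt[1, 2] <- wt[2, 1] <- 1
  wt[1, 3] <- wt[3, 1] <- 1
  wt[2, 3] <- wt[3, 2] <- 0.125
  expect_equal(clusteringCoefficient(wt)[1], 0.5)
})

test_that("local efficiency handles canonical graphs", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  expect_equal(localEfficiency(tri), rep(1, 3))

  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- 1
  p3[2, 3] <- p3[3, 2] <- 1
  expect_identical(localEfficiency(p3)[2], 0)  # neighbours unconnected
})

test_that("betweenness handles canonical graphs", {
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- 1
  p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(betweennessCentrality(p3), c(0, 1, 0))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(betweennessCentrality(star), c(3, 0, 0, 0))

  expect_identical(betweennessCentrality(matrix(0, 5, 5)), rep(0, 5))
})

test_that("all four metrics match brute-force oracles on random graphs", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    W <- randomAdjacency(n, density = runif(1, 0.3, 0.9))
    expect_equal(nodeStrength(W), bruteStrength(W), tolerance = 1e-12)
    expect_equal(clusteringCoefficient(W), bruteClustering(W),
                 tolerance = 1e-12)
    expect_equal(localEfficiency(W), bruteLocalEfficiency(W),
                 tolerance = 1e-12)
    expect_equal(betweennessCentrality(W), bruteBetweenness(W),
                 tolerance = 1e-10)
  }
})

test_that("metrics reduce to textbook values on binary graphs", {
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    W <- randomAdjacency(n, density = 0.6, weighted = FALSE)
    # binary clustering: triangles over connected triples
    A <- (W > 0) * 1
    tri <- diag(A %*% A %*% A)
    k <- rowSums(A)
    cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
    expect_equal(clusteringCoefficient(W), cc)
    expect_equal(betweennessCentrality(W), bruteBetweenness(W),
                 tolerance = 1e-10)
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(23)
  W <- randomAdjacency(7, density = 0.7)
  perm <- sample(7)
  Wp <- W[perm, perm]
  for (f in list(nodeStrength, clusteringCoefficient, localEfficiency,
                 betweennessCentrality))
    expect_equal(f(Wp), f(W)[perm], tolerance = 1e-10)
})

test_that("node strength is monotone in any single edge weight", {
  set.seed(24)
  W <- randomAdjacency(6, density = 0.8)
  s0 <- nodeStrength(W)
  W2 <- W
  W2[2, 5] <- W2[5, 2] <- W2[2, 5] + 0.3
  s1 <- nodeStrength(W2)
  expect_true(all(s1 >= s0 - 1e-15))
  expect_gt(s1[2], s0[2])
})

test_that("metric tables compose the individual metrics", {
  set.seed(25)
  m <- matrix(runif(36), 6); m <- (m + t(m)) / 2; diag(m) <- 1
  fc <- new("StaticFC", matrix = m, scaleIndex = 3L, regionIds = 1:6)
  tab <- computeMetricTable(fc, 0.3)
  W <- applyThreshold(m, 0.3)
  expect_equal(tab$value[tab$metric == "node_strength"], nodeStrength(W))
  expect_equal(tab$value[tab$metric == "clustering_coefficient"],
               clusteringCoefficient(W))
  expect_identical(unique(tab$scale), 3L)

  # dynamic case on a time-constant series reproduces the static table
  r <- array(rep(m, 4), c(6, 6, 4))
  sync <- new("SyncSeries", r = r, scaleIndex = 3L, regionIds = 1:6)
  dyn <- computeMetricTable(sync, 0.3)
  for (t in 1:4)
    expect_equal(dyn$value[dyn$timepoint == t], tab$value)
})
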