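test_that("circular orientation distance handles the axial wraparound", {
  expect_equal(circularThetaDistance(10, 170), 20)
  expect_equal(circularThetaDistance(0, 90), 90)
  expect_equal(circularThetaDistance(45, 45), 0)
  expect_equal(circularThetaDistance(c(0, 179), c(179, 0)), c(1, 1))
})

test_that("scaled feature distance normalizes by the cutoffs", {
  cfg <- clusteringConfig()
  expect_equal(scaledDistance(c(30, 1.5), c(30, 1.5), cfg), 0)
  expect_equal(scaledDistance(c(30, 1.5), c(35, 1.5), cfg), 1)
  expect_equal(scaledDistance(c(30, 1.5), c(35, 1.7), cfg), sqrt(2))
})

test_that("feature grid conserves pixels and orders nodes canonically", {
  set.seed(4)
  th <- stats::runif(500, 0, 180)
  gm <- stats::runif(500, 0, 5)
  grid <- featureGrid(th, gm)
  expect_equal(sum(grid@weight), 500)
  expect_equal(grid@nTotal, 500)
  # theta-major, then gamma
  o <- order(grid@theta, grid@gamma)
  expect_identical(o, seq_along(o))
  # back-references consistent
  expect_true(all(abs(grid@theta[grid@pixelNode] - th) <= 0.5 + 1e-12))
})

test_that("two tight blobs give two full clusters", {
  set.seed(7)
  th <- c(30 + stats::rnorm(100, 0, 0.2), 120 + stats::rnorm(100, 0, 0.2))
  gm <- c(1.5 + stats::rnorm(100, 0, 0.01),
          2.5 + stats::rnorm(100, 0, 0.01))
  res <- clusterPixels(th, gm)
  expect_equal(nClusters(res$model), 2L)
  expect_equal(sort(occupancies(res$model)), c(100, 100))
  # identical partition to the brute-force raw-point oracle
  expect_true(samePartition(res$pixelLabels, oracleDPC(th, gm)))
})

test_that("identical pixels collapse to a single full cluster", {
  res <- clusterPixels(rep(40, 250), rep(1.8, 250))
  expect_equal(nClusters(res$model), 1L)
  expect_equal(occupancies(res$model), 250)
  expect_equal(fibrilEntropy(res$model), 0)
})

test_that("far-apart singletons fall below the element threshold", {
  # 100 mutually separated points, ET = 1% of 100 = 1 element: local
  # density never strictly exceeds the threshold, so nothing is retained
  pts <- expand.grid(th = seq(5, 170, length.out = 10),
                     gm = seq(0.5, 6, length.out = 10))
  res <- clusterPixels(pts$th, pts$gm)
  expect_equal(nClusters(res$model), 0L)
  expect_true(all(is.na(res$pixelLabels)))
  expect_true(samePartition(res$pixelLabels, oracleDPC(pts$th, pts$gm)))
})

test_that("grid clustering matches the raw-point oracle as bins shrink", {
  set.seed(12)
  fineCfg <- clusteringConfig(thetaBin = 1e-6, gammaBin = 1e-7)
  for (i in 1:6) {
    nb <- sample(2:4, 1)
    n <- sample(60:150, 1)
    centers <- cbind(stats::runif(nb, 10, 170), stats::runif(nb, 0.8, 4))
    pick <- sample(nb, n, replace = TRUE)
    th <- (centers[pick, 1] + stats::rnorm(n, 0, 2)) %% 180
    gm <- pmax(centers[pick, 2] + stats::rnorm(n, 0, 0.08), 0)
    res <- clusterPixels(th, gm, fineCfg)
    expect_true(samePartition(res$pixelLabels, oracleDPC(th, gm)))
  }
})

test_that("pruning enforces the per-axis cutoffs", {
  # one declared center; elements at 7 degrees exceed thetaC = 5
  cfg <- clusteringConfig()
  th <- c(rep(30, 40), rep(37, 10))
  gm <- rep(1.5, 50)
  grid <- featureGrid(th, gm, cfg)
  model <- new("ClusterModel",
    centerNode = which.max(grid@weight),
    centerTheta = grid@theta[which.max(grid@weight)],
    centerGamma = grid@gamma[which.max(grid@weight)],
    nodeLabels = rep(1L, length(grid@theta)),
    occupancies = 50, nTotal = 50, pruned = FALSE
  )
  pruned <- pruneClusters(model, grid, cfg)
  expect_equal(occupancies(pruned), 40)
  # idempotence when nothing violates the rules
  again <- pruneClusters(pruned, grid, cfg)
  expect_equal(occupancies(again), occupancies(pruned))
  expect_identical(again@nodeLabels, pruned@nodeLabels)
})

test_that("clusters at exactly the element threshold are removed", {
  # occupancy exactly ET * total fails the strict 'higher than' rule
  cfg <- clusteringConfig(et = 0.1)
  th <- c(rep(30, 10), rep(120, 90))
  gm <- rep(1.5, 100)
  grid <- featureGrid(th, gm, cfg)
  model <- densityPeakCluster(grid, cfg)
  pruned <- pruneClusters(model, grid, cfg)
  expect_equal(occupancies(pruned), 90)
})

test_that("raising the element threshold never adds clusters", {
  set.seed(9)
  n <- 400
  th <- (sample(c(20, 60, 100, 150), n, replace = TRUE,
                prob = c(0.4, 0.3, 0.2, 0.1)) +
           stats::rnorm(n, 0, 2)) %% 180
  gm <- pmax(stats::rnorm(n, 1.8, 0.1), 0)
  ets <- c(0.005, 0.01, 0.05, 0.1, 0.3)
  ks <- vapply(ets, function(et) {
    nClusters(clusterPixels(th, gm, clusteringConfig(et = et))$model)
  }, 0L)
  expect_true(all(diff(ks) <= 0))
})

test_that("clustering is deterministic and permutation-invariant", {
  set.seed(15)
  th <- stats::runif(300, 0, 180)
  gm <- stats::runif(300, 0.5, 3)
  a <- clusterPixels(th, gm)
  b <- clusterPixels(th, gm)
  expect_identical(a$pixelLabels, b$pixelLabels)
  perm <- sample(300)
  p <- clusterPixels(th[perm], gm[perm])
  expect_true(samePartition(a$pixelLabels[perm], p$pixelLabels))
})
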