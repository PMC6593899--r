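test_that("DFT phasor reproduces orthogonality cases", {
  n <- 0:7
  expect_equal(dftPhasor(1 + cos(2 * pi * n / 8)), c(g = 0.5, s = 0))
  expect_equal(dftPhasor(1 + sin(2 * pi * n / 8)), c(g = 0, s = 0.5))
  expect_equal(dftPhasor(rep(2, 8)), c(g = 0, s = 0))
})

test_that("phasor transform rejects degenerate input", {
  expect_error(dftPhasor(rep(0, 8)), "all-zero")
  expect_error(dftPhasor(c(1, 2), harmonic = 1L), "too short")
  expect_error(dftPhasor(c(1, -1, 1, 1)), "nonnegative")
})

test_that("phasor coordinates of nonnegative signals stay in unit disk", {
  set.seed(11)
  for (i in 1:50) {
    sig <- stats::runif(36, 0, 10)
    for (m in 1:3) {
      p <- dftPhasor(sig, m)
      expect_lte(p["g"]^2 + p["s"]^2, 1 + 1e-12)
    }
  }
})

test_that("theta reference curve is a closed loop with linear phase", {
  ref <- buildThetaReference(thetaSamples = 360L)
  expect_length(ref@param, 360L)
  # entry at thetaF = 0: even cos^4 signal, phase 0 (positive-g axis)
  i0 <- which(ref@param == 0)
  expect_equal(ref@s[i0], 0, tolerance = 1e-12)
  expect_gt(ref@g[i0], 0)
  # advancing thetaF by 45 degrees rotates the phasor phase by a quarter
  # turn (DFT shift theorem)
  i45 <- which(ref@param == 45)
  dphi <- atan2(ref@s[i45], ref@g[i45]) - atan2(ref@s[i0], ref@g[i0])
  expect_equal(abs(dphi) %% (2 * pi), pi / 2, tolerance = 1e-9)
  # closed loop: radius constant, endpoints meet
  rad <- sqrt(ref@g^2 + ref@s^2)
  expect_lt(diff(range(rad)), 1e-9)
  expect_lt(
    (ref@g[360] - ref@g[1])^2 + (ref@s[360] - ref@s[1])^2,
    (2 * pi / 360 * rad[1] * 1.1)^2
  )
})

test_that("gamma reference curve is injective and scale-free", {
  ref <- buildGammaReference()
  expect_length(ref@param, 1001L)
  # injective lookup: distinct gammas map to distinct coordinates
  d <- sqrt(diff(ref@g)^2 + diff(ref@s)^2)
  expect_gt(min(d), 0)
  # gamma = 1 entry equals the phasor of 1 + sin^2(2 delta) on the window
  win <- seq(0, 90 - 90 / 16, length.out = 16L)
  expected <- dftPhasor(1 + sin(2 * win * pi / 180)^2)
  i1 <- which(abs(ref@param - 1) < 1e-9)
  expect_equal(c(g = ref@g[i1], s = ref@s[i1]), expected)
  # the intensity scale cancels: k = 1 and k = 7 give identical curves
  refK <- vapply(c(0.5, 1.83, 7), function(gm) {
    dftPhasor(shgIntensity(win, 0, gm, k = 7))
  }, c(g = 0, s = 0))
  for (j in seq_along(c(0.5, 1.83, 7))) {
    gm <- c(0.5, 1.83, 7)[j]
    i <- which(abs(ref@param - gm) < 1e-9)
    expect_equal(c(g = ref@g[i], s = ref@s[i]), refK[, j],
                 tolerance = 1e-12)
  }
})

test_that("single-pixel retrieval inverts the forward model", {
  # frozen expectations from the exhaustive least-squares oracle
  r <- retrievePixel(simulateResponse(30, gamma = 2, k = 1))
  expect_lt(circularThetaDistance(r$theta, 30), 1)
  expect_lt(abs(r$gamma - 2), 0.05)
  # gamma < 1 branch (first harmonic changes sign)
  r2 <- retrievePixel(simulateResponse(150, gamma = 0.8, k = 3))
  expect_lt(circularThetaDistance(r2$theta, 150), 2)
  expect_lt(abs(r2$gamma - 0.8), 0.05)
  # constant signal: no harmonic content, flagged invalid
  r3 <- retrievePixel(rep(5, 36))
  expect_false(r3$valid)
})

test_that("retrieval agrees with the brute-force least-squares oracle", {
  set.seed(3)
  ang <- defaultAngles()
  for (i in 1:25) {
    thF <- stats::runif(1, 0, 180)
    gm <- stats::runif(1, 0.3, 6)
    if (abs(gm - 1) < 0.1) gm <- gm + 0.2 # skip the degenerate band
    sig <- shgIntensity(ang, thF, gm, k = stats::runif(1, 0.5, 3))
    r <- retrievePixel(sig, ang)
    o <- oracleRetrieve(sig, ang)
    expect_lt(circularThetaDistance(r$theta, o["theta"]), 0.5)
    # oracle grid step (0.02) + lookup grid (0.01) + window interpolation
    expect_lt(abs(r$gamma - o["gamma"]), 0.06)
  }
})

test_that("noiseless round trip recovers theta and gamma", {
  ang <- defaultAngles()
  thetaRef <- buildThetaReference(ang)
  gammaRef <- buildGammaReference()
  for (thF in seq(0, 165, by = 15)) {
    for (gm in c(0.8, 1.2, 1.77, 1.83, 2.5, 3.5, 4.5)) {
      sig <- shgIntensity(ang, thF, gm)
      r <- retrievePixel(sig, ang, thetaRef, gammaRef)
      expect_lte(circularThetaDistance(r$theta, thF), 2)
      expect_lte(abs(r$gamma - gm), 0.1)
    }
  }
})

test_that("retrieval output is invariant under intensity rescaling", {
  sig <- simulateResponse(77.3, gamma = 2.6, k = 1)
  a <- retrievePixel(sig)
  b <- retrievePixel(sig * 40)
  expect_lt(circularThetaDistance(a$theta, b$theta), 1e-6)
  expect_lt(abs(a$gamma - b$gamma), 0.011)
})

test_that("gamma = 1 pixels are retained and flagged degenerate", {
  r <- retrievePixel(simulateResponse(63, gamma = 1))
  expect_true(r$valid)
  expect_true(r$degenerate)
  # orientation defined modulo 90 degrees
  d <- abs(r$theta - 63 %% 90) %% 90
  expect_lt(min(d, 90 - d), 2)
  expect_lt(abs(r$gamma - 1), 0.05)
})

test_that("whole-image retrieval builds maps and phasor plots", {
  nl <- noiselessPhantom()
  ret <- retrieveMaps(nl$stack)
  maps <- ret$maps
  expect_gte(mean(validMask(maps)), 0.99)
  ok <- validMask(maps)
  expect_lt(max(circularThetaDistance(thetaMap(maps)[ok], 30)), 2)
  expect_lt(max(abs(gammaMap(maps)[ok] - 2)), 0.1)
  # phasor plot counts equal valid pixels
  expect_equal(sum(ret$thetaPlot@counts), sum(ok))
  expect_equal(sum(ret$gammaPlot@counts), sum(ok))
  # stack of zeros: no valid pixels
  z <- polarizationStack(array(0, c(8, 8, 36)))
  rz <- retrieveMaps(z)
  expect_equal(sum(validMask(rz$maps)), 0L)
})
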