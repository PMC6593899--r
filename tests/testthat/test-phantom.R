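test_that("phantom sampling honours the spec and the seed", {
  spec <- phantomSpec(imageShape = c(32L, 32L), pixelSizeUm = 1,
                      backgroundFraction = 0)
  a <- makePhantom(spec, seed = 2)
  b <- makePhantom(spec, seed = 2)
  expect_identical(thetaMap(a$truth), thetaMap(b$truth))
  expect_identical(gammaMap(a$truth), gammaMap(b$truth))
  expect_identical(a$k, b$k)
  cc <- makePhantom(spec, seed = 3)
  expect_false(identical(thetaMap(a$truth), thetaMap(cc$truth)))
  # equal split geometry
  expect_equal(sum(a$regionMask), 32 * 16)
  # zero-SD single mode collapses to one (theta, gamma) value
  nl <- noiselessPhantom()
  expect_true(all(thetaMap(nl$phantom$truth) == 30))
  expect_true(all(gammaMap(nl$phantom$truth) == 2))
})

test_that("degenerate geometry is rejected", {
  expect_error(makePhantom(phantomSpec(imageShape = c(1L, 1L))),
               "degenerate")
})

test_that("rendered stacks are reproducible and truth-consistent", {
  nl <- noiselessPhantom()
  # noiseless render equals the forward model at each pixel
  expect_equal(
    nl$stack@data[3, 7, ],
    shgIntensity(angles(nl$stack), 30, 2, k = nl$phantom$k[3, 7])
  )
  # Poisson render is bitwise reproducible under the seed
  spec <- phantomSpec(imageShape = c(16L, 16L), pixelSizeUm = 1)
  ph <- makePhantom(spec, seed = 4)
  s1 <- renderStack(ph, seed = 9)
  s2 <- renderStack(ph, seed = 9)
  expect_identical(s1@data, s2@data)
  expect_false(identical(s1@data, renderStack(ph, seed = 10)@data))
})

test_that("noiseless phantom round-trips through retrieval everywhere", {
  nl <- noiselessPhantom()
  ret <- retrieveMaps(nl$stack)
  ok <- validMask(ret$maps)
  expect_gte(mean(ok), 0.99)
  expect_lte(max(circularThetaDistance(thetaMap(ret$maps)[ok], 30)), 2)
  expect_lte(max(abs(gammaMap(ret$maps)[ok] - 2)), 0.1)
})

test_that("background-only phantom yields no valid pixels", {
  spec <- phantomSpec(imageShape = c(16L, 16L), pixelSizeUm = 1,
                      backgroundFraction = 1)
  ph <- makePhantom(spec, seed = 6)
  stack <- renderStack(ph, seed = 6)
  ret <- retrieveMaps(stack)
  expect_equal(sum(validMask(ret$maps)), 0L)
})

test_that("two-region phantom separates the architectures end to end", {
  full <- defaultPhantomAnalysis()
  tab <- full$analysis@table
  splitCol <- ncol(thetaMap(full$maps)) / 2
  ordered <- tab$col < splitCol
  ordTab <- tab[ordered & tab$valid, ]
  disTab <- tab[!ordered & tab$valid, ]
  # disordered tissue has more clusters on average
  expect_gt(mean(disTab$nClusters), mean(ordTab$nClusters))
  # matched ROI positions: entropy higher in the disordered region
  key <- function(d) d[order(d$row, d$col %% splitCol), ]
  ordM <- key(ordTab)
  disM <- key(disTab)
  n <- min(nrow(ordM), nrow(disM))
  frac <- mean(disM$entropy[seq_len(n)] > ordM$entropy[seq_len(n)])
  expect_gte(frac, 0.9)
  # per-region gamma medians track the generating distributions
  ok <- validMask(full$maps)
  gmap <- gammaMap(full$maps)
  mOrd <- stats::median(gmap[ok & !full$phantom$regionMask])
  mDis <- stats::median(gmap[ok & full$phantom$regionMask])
  expect_lt(abs(mOrd - 1.83), 0.1)
  expect_lt(abs(mDis - 1.77), 0.1)
})
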