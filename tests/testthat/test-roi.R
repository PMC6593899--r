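test_that("tiling is non-overlapping, row-major, edge tiles dropped", {
  g <- tileGrid(c(400, 300), roiSizeUm = 100, pixelSizeUm = 1)
  expect_equal(nrow(g@rects), 12L)
  expect_equal(g@dim, c(4L, 3L))
  # the standard acquisition geometry: 512 px at 377/512 um, 150 um ROI
  g2 <- tileGrid(c(512, 512), roiSizeUm = 150)
  expect_equal(g2@roiSizePx, 203L)
  expect_equal(nrow(g2@rects), 4L)
  expect_error(tileGrid(c(100, 100), roiSizeUm = 101, pixelSizeUm = 1),
               "larger than image")
  # partition: tiles disjoint, within the image
  cover <- matrix(0L, 400, 300)
  for (i in seq_len(nrow(g@rects))) {
    r <- g@rects[i, ]
    cover[(r$row + 1):(r$row + r$height),
          (r$col + 1):(r$col + r$width)] <-
      cover[(r$row + 1):(r$row + r$height),
            (r$col + 1):(r$col + r$width)] + 1L
  }
  expect_lte(max(cover), 1L)
  expect_lte(sum(cover), 400 * 300)
})

# build MicroMaps directly from value matrices
mapsFrom <- function(th, gm) {
  valid <- !is.na(th)
  new("MicroMaps",
    theta = th, gamma = gm, valid = valid,
    degenerate = matrix(FALSE, nrow(th), ncol(th)),
    meanIntensity = matrix(1, nrow(th), ncol(th)), pixelSize = 1
  )
}

test_that("a single tight blob ROI has one cluster and zero entropy", {
  th <- matrix(40, 60, 60)
  gm <- matrix(1.8, 60, 60)
  maps <- mapsFrom(th, gm)
  g <- tileGrid(c(60, 60), roiSizeUm = 60, pixelSizeUm = 1)
  an <- analyzeSection(maps, g, minMainCluster = 30)
  expect_equal(an@table$nClusters, 1L)
  expect_equal(an@table$entropy, 0)
  expect_true(an@table$valid)
})

test_that("scattered pixels under a high threshold invalidate the ROI", {
  set.seed(31)
  n <- 30
  th <- matrix(stats::runif(n * n, 0, 180), n, n)
  gm <- matrix(stats::runif(n * n, 0, 8), n, n)
  maps <- mapsFrom(th, gm)
  g <- tileGrid(c(n, n), roiSizeUm = n, pixelSizeUm = 1)
  an <- analyzeSection(maps, g, clusteringConfig(et = 0.3),
                       minMainCluster = 15)
  expect_false(an@table$valid)
  expect_error(entropyThreshold(an), "no valid ROIs")
})

test_that("entropy threshold is the mean over valid ROIs", {
  tab <- data.frame(
    roi = 1:4, row = 0, col = 0, nValidPixels = 10, nClusters = 2L,
    entropy = c(0.2, 0.4, 0.6, 0.9), cerPct = 0, mainCluster = 10,
    valid = c(TRUE, TRUE, TRUE, FALSE)
  )
  an <- new("ROIAnalysis", table = tab,
            roiGrid = tileGrid(c(10, 10), 10, 1), cerThreshold = 0.6,
            minMainCluster = 15, config = clusteringConfig())
  expect_equal(entropyThreshold(an), 0.4)
})

test_that("segmentation back-projects ROI labels with ties going low", {
  set.seed(33)
  right <- matrix(stats::runif(800, 0, 180), 40, 20)
  right[sample(800, 100)] <- NA_real_
  th <- cbind(matrix(30, 40, 20), right)
  gm <- th * 0 + 1.8
  gm[, 21:40] <- ifelse(is.na(right), NA, stats::runif(800, 0, 6))
  maps <- mapsFrom(th, gm)
  g <- tileGrid(c(40, 40), roiSizeUm = 20, pixelSizeUm = 1)
  an <- analyzeSection(maps, g, clusteringConfig(et = 0.01),
                       minMainCluster = 15)
  sTh <- entropyThreshold(an)
  seg <- segmentSection(an, sTh)
  expect_true(all(seg@mask %in% 0:2))
  # the ordered ROIs (left) have entropy 0 <= sTh: labeled low
  expect_true(all(seg@mask[, 1:20] %in% c(0L, 1L)))
  # an ROI exactly at the threshold is low (strict 'above')
  one <- an@table[an@table$valid, ][1, ]
  segTie <- segmentSection(an, sTh = one$entropy)
  rows <- (one$row + 1):(one$row + 20)
  cols <- (one$col + 1):(one$col + 20)
  expect_true(all(segTie@mask[rows, cols] == 1L))
})

test_that("threshold lies between the extreme ROI entropies", {
  full <- defaultPhantomAnalysis()
  an <- full$analysis
  s <- an@table$entropy[an@table$valid]
  sTh <- entropyThreshold(an)
  expect_gte(sTh, min(s))
  expect_lte(sTh, max(s))
})

test_that("accuracy scoring counts per-class agreement", {
  g <- tileGrid(c(20, 20), 10, 1)
  mk <- function(maskVals) {
    new("SegmentationResult", mask = maskVals, sTh = 0.5,
        entropyMap = matrix(NA_real_, 2, 2), roiGrid = g)
  }
  ref <- cbind(matrix(FALSE, 20, 10), matrix(TRUE, 20, 10))
  perfect <- mk(cbind(matrix(1L, 20, 10), matrix(2L, 20, 10)))
  acc <- segmentationAccuracy(perfect, ref)
  expect_equal(acc$low, 100)
  expect_equal(acc$high, 100)
  expect_equal(acc$combined, 100)
  flipped <- mk(cbind(matrix(2L, 20, 10), matrix(1L, 20, 10)))
  acc2 <- segmentationAccuracy(flipped, ref)
  expect_equal(acc2$combined, 0)
  # half of the high class mislabeled: 50% for that class
  half <- cbind(matrix(1L, 20, 10), rbind(matrix(2L, 10, 10),
                                          matrix(1L, 10, 10)))
  acc3 <- segmentationAccuracy(mk(half), ref)
  expect_equal(acc3$high, 50)
  expect_equal(acc3$low, 100)
  # unclassified pixels excluded from numerator and denominator
  part <- cbind(matrix(0L, 20, 10), matrix(2L, 20, 10))
  acc4 <- segmentationAccuracy(mk(part), ref)
  expect_equal(acc4$high, 100)
  expect_true(is.na(acc4$low))
  expect_error(segmentationAccuracy(perfect, ref[1:10, ]), "mismatch")
})
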