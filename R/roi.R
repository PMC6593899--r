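#' Tile an image into non-overlapping square ROIs
#'
#' Builds a sequential, non-overlapping row-major tiling from the image
#' origin with square tiles of `roiSizeUm` micrometres, converted to whole
#' pixels by `floor(roiSizeUm / pixelSizeUm)`. Partial edge tiles are
#' dropped.
#'
#' @param imageShape image height and width in pixels, `c(h, w)`.
#' @param roiSizeUm tile side in micrometres (75 and 150 are the standard
#'   choices).
#' @param pixelSizeUm pixel side in micrometres.
#' @return an [ROIGrid].
#' @examples
#' tileGrid(c(400, 300), roiSizeUm = 100, pixelSizeUm = 1)@dim # 4 x 3
#' @export
tileGrid <- function(imageShape, roiSizeUm, pixelSizeUm = 377 / 512) {
  if (roiSizeUm < 2 * pixelSizeUm) {
    stop("'roiSizeUm' must be at least two pixels", call. = FALSE)
  }
  px <- as.integer(floor(roiSizeUm / pixelSizeUm))
  h <- as.integer(imageShape[1L])
  w <- as.integer(imageShape[2L])
  if (px > h || px > w) {
    stop("ROI larger than image", call. = FALSE)
  }
  nr <- h %/% px
  nc <- w %/% px
  rects <- expand.grid(colIdx = seq_len(nc) - 1L, rowIdx = seq_len(nr) - 1L)
  rects <- data.frame(
    row = rects$rowIdx * px, col = rects$colIdx * px,
    height = px, width = px
  )
  new("ROIGrid", roiSizeUm = roiSizeUm, roiSizePx = px, rects = rects,
      imageShape = c(h, w), dim = c(nr, nc))
}

#' Per-ROI clustering and descriptor computation over a section
#'
#' Runs density-peak clustering (with pruning) on the valid pixels of every
#' ROI of the tiling and computes the three descriptors per ROI. The element
#' threshold is applied per ROI, as a fraction of that ROI's valid pixels.
#' An ROI is invalid when its main (most populated) cluster holds fewer than
#' `minMainCluster` elements; invalid ROIs are excluded from the entropy
#' threshold and carry `NA` in the maps.
#'
#' @param maps a [MicroMaps].
#' @param grid an [ROIGrid] over the same image frame.
#' @param config a [ClusteringConfig].
#' @param minMainCluster minimum main-cluster occupancy for a valid ROI.
#'   Defaults to 30 for 150-micrometre tiles and 15 for 75-micrometre tiles
#'   (scaled linearly with tile side otherwise).
#' @param cerThreshold CER threshold for the cumulative-percentage map.
#' @return an [ROIAnalysis].
#' @seealso [entropyThreshold()], [segmentSection()], [roiMap()]
#' @export
analyzeSection <- function(maps, grid, config = clusteringConfig(),
                           minMainCluster = NULL, cerThreshold = 0.6) {
  stopifnot(is(maps, "MicroMaps"), is(grid, "ROIGrid"))
  if (!all(dim(maps@theta) == grid@imageShape)) {
    stop("maps and ROI grid must share the image frame", call. = FALSE)
  }
  if (is.null(minMainCluster)) {
    minMainCluster <- 15 * grid@roiSizeUm / 75
  }
  rects <- grid@rects
  n <- nrow(rects)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rects[i, ]
    rows <- (r$row + 1L):(r$row + r$height)
    cols <- (r$col + 1L):(r$col + r$width)
    th <- maps@theta[rows, cols]
    gm <- maps@gamma[rows, cols]
    ok <- maps@valid[rows, cols]
    nv <- sum(ok)
    if (nv == 0L) {
      res[[i]] <- data.frame(nValidPixels = 0, nClusters = 0L,
                             entropy = NA_real_, cerPct = NA_real_,
                             mainCluster = 0, valid = FALSE)
      next
    }
    cl <- clusterPixels(th[ok], gm[ok], config)
    pp <- pParams(cl$model)
    main <- if (pp@nClusters > 0L) max(cl$model@occupancies) else 0
    res[[i]] <- data.frame(
      nValidPixels = nv,
      nClusters = pp@nClusters,
      entropy = pp@entropy,
      cerPct = if (pp@nClusters > 0L) {
        cerCumulative(pp@cer, cerThreshold)
      } else {
        NA_real_
      },
      mainCluster = main,
      valid = pp@nClusters > 0L && main >= minMainCluster
    )
  }
  tab <- do.call(rbind, res)
  tab <- cbind(
    data.frame(roi = seq_len(n), row = rects$row, col = rects$col),
    tab
  )
  new("ROIAnalysis", table = tab, roiGrid = grid,
      cerThreshold = cerThreshold, minMainCluster = minMainCluster,
      config = config)
}

#' ROI-resolution map of a per-ROI descriptor
#'
#' Extracts one descriptor column of an [ROIAnalysis] as a matrix with one
#' cell per ROI (tile-row by tile-column); invalid ROIs carry `NA`.
#'
#' @param analysis an [ROIAnalysis].
#' @param what one of `"entropy"`, `"nClusters"`, `"cerPct"`.
#' @return numeric matrix of tiling dimensions.
#' @export
roiMap <- function(analysis, what = c("entropy", "nClusters", "cerPct")) {
  what <- match.arg(what)
  tab <- analysis@table
  v <- tab[[what]]
  v[!tab$valid] <- NA_real_
  # rects are row-major
  matrix(v, nrow = analysis@roiGrid@dim[1L],
         ncol = analysis@roiGrid@dim[2L], byrow = TRUE)
}

#' Section-wide entropy threshold
#'
#' The segmentation threshold: the arithmetic mean of the fibril entropy
#' over all valid ROIs of the section.
#'
#' @param analysis an [ROIAnalysis].
#' @return the threshold `S_th`.
#' @export
entropyThreshold <- function(analysis) {
  stopifnot(is(analysis, "ROIAnalysis"))
  tab <- analysis@table
  s <- tab$entropy[tab$valid]
  if (length(s) == 0L) {
    stop("no valid ROIs to compute an entropy threshold from",
         call. = FALSE)
  }
  mean(s)
}

#' Entropy-threshold segmentation by back-projection
#'
#' Labels every valid ROI high-entropy when its fibril entropy is strictly
#' above the threshold (low-entropy at or below, ties low), then
#' back-projects the ROI label to all of its pixels. Pixels of invalid ROIs
#' and pixels outside the tiling remain unclassified.
#'
#' @param analysis an [ROIAnalysis].
#' @param sTh entropy threshold; defaults to [entropyThreshold()] of the
#'   section.
#' @return a [SegmentationResult] with mask values 0 (unclassified),
#'   1 (low entropy), 2 (high entropy).
#' @export
segmentSection <- function(analysis, sTh = entropyThreshold(analysis)) {
  stopifnot(is(analysis, "ROIAnalysis"), is.finite(sTh))
  grid <- analysis@roiGrid
  tab <- analysis@table
  mask <- matrix(0L, grid@imageShape[1L], grid@imageShape[2L])
  for (i in seq_len(nrow(tab))) {
    if (!tab$valid[i]) next
    lab <- if (tab$entropy[i] > sTh) 2L else 1L
    rows <- (tab$row[i] + 1L):(tab$row[i] + grid@roiSizePx)
    cols <- (tab$col[i] + 1L):(tab$col[i] + grid@roiSizePx)
    mask[rows, cols] <- lab
  }
  new("SegmentationResult", mask = mask, sTh = sTh,
      entropyMap = roiMap(analysis, "entropy"), roiGrid = grid)
}

#' Segmentation accuracy against a reference mask
#'
#' Percentage of correctly labeled pixels per class and combined, comparing
#' the entropy-based segmentation with a binary reference (e.g. an expert
#' delineation or a phantom's ground-truth region mask, `TRUE` marking the
#' disordered / high-entropy region). Unclassified pixels are excluded from
#' both numerator and denominator.
#'
#' @param segmentation a [SegmentationResult].
#' @param reference logical matrix of the same shape.
#' @return list with `low`, `high` and `combined` percentages.
#' @export
segmentationAccuracy <- function(segmentation, reference) {
  stopifnot(is(segmentation, "SegmentationResult"))
  mask <- segmentation@mask
  if (!all(dim(reference) == dim(mask))) {
    stop("reference mask shape mismatch", call. = FALSE)
  }
  reference <- matrix(as.logical(reference), nrow(mask), ncol(mask))
  cls <- mask > 0L
  nLow <- sum(cls & !reference)
  nHigh <- sum(cls & reference)
  okLow <- sum(mask == 1L & !reference)
  okHigh <- sum(mask == 2L & reference)
  list(
    low = if (nLow > 0) 100 * okLow / nLow else NA_real_,
    high = if (nHigh > 0) 100 * okHigh / nHigh else NA_real_,
    combined = if (sum(cls) > 0) {
      100 * (okLow + okHigh) / sum(cls)
    } else {
      NA_real_
    }
  )
}
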