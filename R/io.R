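# file I/O: TIFF stacks with JSON sidecars, map export, CSV tables.
# 32-bit float TIFF storage is normalized into [0, 1] by a power-of-two
# scale recorded in the sidecar, so integer photon counts round-trip
# exactly.

scalePow2 <- function(m) {
  if (!is.finite(m) || m <= 0) {
    return(1)
  }
  2^ceiling(log2(m))
}

sidecarPath <- function(path) {
  sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
}

#' Write a polarization stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are stored in angle order as 32-bit floats; the sidecar records
#' `angles_deg`, `pixel_size_um` and the intensity scale.
#'
#' @param stack a [PolarizationStack].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "PolarizationStack"))
  sc <- scalePow2(max(stack@data))
  pages <- lapply(seq_along(stack@angles), function(i) {
    stack@data[, , i] / sc
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(angles_deg = stack@angles, pixel_size_um = stack@pixelSize,
         intensity_scale = sc,
         integer_counts = all(stack@data == round(stack@data))),
    sidecarPath(path),
    auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read a polarization stack from multi-page TIFF plus JSON sidecar
#'
#' @param path TIFF path (page order = angle order).
#' @param sidecar sidecar JSON path; defaults to `path` with a `.json`
#'   extension.
#' @return a [PolarizationStack].
#' @export
readStack <- function(path, sidecar = sidecarPath(path)) {
  if (!file.exists(sidecar)) {
    stop("missing sidecar file: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) {
    pages <- list(pages)
  }
  angles <- as.numeric(meta$angles_deg)
  if (length(pages) != length(angles)) {
    stop(sprintf("TIFF has %d pages but sidecar lists %d angles",
                 length(pages), length(angles)), call. = FALSE)
  }
  stopIfBadGrid(angles)
  sc <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  h <- nrow(pages[[1L]])
  w <- ncol(pages[[1L]])
  data <- array(0, c(h, w, length(pages)))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) {
      pg <- pg[, , 1L]
    }
    if (nrow(pg) != h || ncol(pg) != w) {
      stop("TIFF pages have inconsistent dimensions", call. = FALSE)
    }
    data[, , i] <- pg * sc
  }
  # photon-count stacks are stored losslessly up to quantization below 0.5
  if (isTRUE(as.logical(meta$integer_counts[1L]))) {
    data <- round(data)
  }
  polarizationStack(data, angles,
                    pixelSize = as.numeric(meta$pixel_size_um))
}

#' Export retrieved maps as single-page 32-bit TIFFs
#'
#' Writes `theta.tif`, `gamma.tif`, `mean_intensity.tif` (each with a JSON
#' sidecar recording the scale; invalid pixels stored as 0) and the boolean
#' masks `valid.tif` and `degenerate.tif`.
#'
#' @param maps a [MicroMaps].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeMaps <- function(maps, dir) {
  stopifnot(is(maps, "MicroMaps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeOne <- function(m, name) {
    m[is.na(m)] <- 0
    sc <- scalePow2(max(m))
    tiff::writeTIFF(m / sc, file.path(dir, paste0(name, ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(scale = sc),
                         file.path(dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  writeOne(maps@theta, "theta")
  writeOne(maps@gamma, "gamma")
  writeOne(maps@meanIntensity, "mean_intensity")
  tiff::writeTIFF(maps@valid * 1, file.path(dir, "valid.tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(maps@degenerate * 1, file.path(dir, "degenerate.tif"),
                  bits.per.sample = 8L)
  invisible(dir)
}

#' Read a binary mask from TIFF or PNG
#'
#' Nonzero pixels are `TRUE`. Used for reference masks in accuracy scoring.
#'
#' @param path TIFF or PNG file.
#' @return logical matrix.
#' @export
readMask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) {
    img <- img[, , 1L]
  }
  img > 0
}

#' Export a phasor plot as CSV
#'
#' One row per occupied bin: g-bin center, s-bin center, count.
#'
#' @param plot a [PhasorPlot].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePhasorPlot <- function(plot, path) {
  stopifnot(is(plot, "PhasorPlot"))
  gC <- (plot@gBreaks[-1L] + plot@gBreaks[-length(plot@gBreaks)]) / 2
  sC <- (plot@sBreaks[-1L] + plot@sBreaks[-length(plot@sBreaks)]) / 2
  occ <- which(plot@counts > 0, arr.ind = TRUE)
  df <- data.frame(g = gC[occ[, 1L]], s = sC[occ[, 2L]],
                   count = plot@counts[occ])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export cluster assignments as CSV and a label map as TIFF
#'
#' The CSV has one row per feature-grid node (`theta_bin`, `gamma_bin`,
#' `weight`, `cluster_id`; 0 = unassigned). When `pixelLabels` and
#' `imageShape` are given, a per-pixel label TIFF is written too (labels
#' scaled into `[0, 1]` by the cluster count).
#'
#' @param clustering result of [clusterPixels()].
#' @param path output CSV path.
#' @param labelTiff optional path of the per-pixel label TIFF.
#' @param imageShape image dimensions for the label map.
#' @return `path`, invisibly.
#' @export
writeClusterModel <- function(clustering, path, labelTiff = NULL,
                              imageShape = NULL) {
  grid <- clustering$grid
  model <- clustering$model
  lab <- model@nodeLabels
  df <- data.frame(
    theta_bin = grid@theta, gamma_bin = grid@gamma,
    weight = grid@weight, cluster_id = ifelse(is.na(lab), 0L, lab)
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(labelTiff) && !is.null(imageShape)) {
    k <- max(1L, length(model@occupancies))
    px <- clustering$pixelLabels
    px[is.na(px)] <- 0L
    tiff::writeTIFF(matrix(px / k, imageShape[1L], imageShape[2L]),
                    labelTiff, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Export a per-ROI descriptor table as CSV
#'
#' @param analysis an [ROIAnalysis].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRoiTable <- function(analysis, path) {
  stopifnot(is(analysis, "ROIAnalysis"))
  utils::write.csv(analysis@table, path, row.names = FALSE)
  invisible(path)
}
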