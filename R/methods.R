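# constructors, accessors and show methods

#' Construct a PolarizationStack
#'
#' @param data numeric H x W x N array of nonnegative intensities.
#' @param angles polarization angles in degrees (one per frame).
#' @param pixelSize pixel side in micrometres.
#' @return a [PolarizationStack].
#' @export
polarizationStack <- function(data, angles = defaultAngles(dim(data)[3L]),
                              pixelSize = 377 / 512) {
  new("PolarizationStack", data = data, angles = angles,
      pixelSize = pixelSize, period = 180)
}

#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' Accessors for shgphasor classes
#'
#' `angles()` returns the polarization angle grid of a stack; `pixelSize()`
#' the pixel size in micrometres; `thetaMap()`, `gammaMap()`, `validMask()`
#' and `meanIntensity()` the per-pixel maps; `nClusters()`, `occupancies()`
#' and `cer()` the cluster descriptors.
#'
#' @param x an object of the documented class.
#' @name accessors
#' @rdname accessors
#' @export
setMethod("angles", "PolarizationStack", function(x) x@angles)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "PolarizationStack", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("pixelSize", "MicroMaps", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setGeneric("thetaMap", function(x) standardGeneric("thetaMap"))

#' @rdname accessors
#' @export
setMethod("thetaMap", "MicroMaps", function(x) x@theta)

#' @rdname accessors
#' @export
setGeneric("gammaMap", function(x) standardGeneric("gammaMap"))

#' @rdname accessors
#' @export
setMethod("gammaMap", "MicroMaps", function(x) x@gamma)

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setMethod("validMask", "MicroMaps", function(x) x@valid)

#' @rdname accessors
#' @export
setGeneric("meanIntensity", function(x) standardGeneric("meanIntensity"))

#' @rdname accessors
#' @export
setMethod("meanIntensity", "MicroMaps", function(x) x@meanIntensity)

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterModel", function(x) length(x@occupancies))

#' @rdname accessors
#' @export
setMethod("nClusters", "PParams", function(x) x@nClusters)

#' @rdname accessors
#' @export
setGeneric("occupancies", function(x) standardGeneric("occupancies"))

#' @rdname accessors
#' @export
setMethod("occupancies", "ClusterModel", function(x) x@occupancies)

#' @rdname accessors
#' @export
setGeneric("cer", function(x) standardGeneric("cer"))

#' @rdname accessors
#' @export
setMethod("cer", "PParams", function(x) x@cer)

#' @rdname accessors
#' @export
setMethod("cer", "ClusterModel", function(x) {
  clusterElementsRatio(x@occupancies)
})

setMethod("show", "PolarizationStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "PolarizationStack: %d x %d px, %d frames (%.1f-%.1f deg, step %.2g)\n",
    d[1L], d[2L], d[3L], min(object@angles), max(object@angles),
    object@angles[2L] - object@angles[1L]
  ))
  cat(sprintf("  pixel size %.4f um\n", object@pixelSize))
})

setMethod("show", "MicroMaps", function(object) {
  nv <- sum(object@valid)
  cat(sprintf(
    "MicroMaps: %d x %d px, %d valid pixels (%.1f%%), %d degenerate\n",
    nrow(object@theta), ncol(object@theta), nv,
    100 * nv / length(object@valid), sum(object@degenerate)
  ))
  if (nv) {
    cat(sprintf(
      "  theta median %.1f deg; gamma median %.2f\n",
      stats::median(object@theta[object@valid]),
      stats::median(object@gamma[object@valid])
    ))
  }
})

setMethod("show", "ReferenceCurve", function(object) {
  cat(sprintf(
    "ReferenceCurve (%s): %d entries, param in [%g, %g]\n",
    object@kind, length(object@param), min(object@param),
    max(object@param)
  ))
})

setMethod("show", "ClusteringConfig", function(object) {
  cat(sprintf(
    "ClusteringConfig: thetaC=%g deg, gammaC=%g, ET=%g%%, dC=%g, bins %g deg x %g\n",
    object@thetaC, object@gammaC, 100 * object@et, object@dC,
    object@thetaBin, object@gammaBin
  ))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf(
    "ClusterModel (%s): %d clusters, %g/%g elements clustered\n",
    if (object@pruned) "pruned" else "unpruned",
    length(object@occupancies), sum(object@occupancies), object@nTotal
  ))
})

setMethod("show", "PParams", function(object) {
  cat(sprintf(
    "PParams: N_C=%d, S=%.4f, E_C=%g\n",
    object@nClusters, object@entropy, object@totalClustered
  ))
})

setMethod("show", "ROIAnalysis", function(object) {
  tab <- object@table
  cat(sprintf(
    "ROIAnalysis: %d x %d ROIs of %g um (%d px), %d valid\n",
    object@roiGrid@dim[1L], object@roiGrid@dim[2L],
    object@roiGrid@roiSizeUm, object@roiGrid@roiSizePx, sum(tab$valid)
  ))
  if (any(tab$valid)) {
    cat(sprintf(
      "  entropy %.3f-%.3f (mean %.3f); N_C %d-%d\n",
      min(tab$entropy[tab$valid]), max(tab$entropy[tab$valid]),
      mean(tab$entropy[tab$valid]),
      min(tab$nClusters[tab$valid]), max(tab$nClusters[tab$valid])
    ))
  }
})

setMethod("show", "SegmentationResult", function(object) {
  m <- object@mask
  cat(sprintf(
    "SegmentationResult: S_th=%.4f; %.1f%% low-S, %.1f%% high-S, %.1f%% unclassified\n",
    object@sTh, 100 * mean(m == 1L), 100 * mean(m == 2L),
    100 * mean(m == 0L)
  ))
})
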