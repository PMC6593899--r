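#' @import methods
NULL

#' PolarizationStack: a polarization-resolved SHG image stack
#'
#' Container for an N-frame stack of 2D SHG intensity images, one frame per
#' laser polarization angle, together with the angular grid (degrees) and the
#' pixel size (micrometres). Frames must be sampled on a strictly increasing,
#' uniformly spaced angle grid covering one period of the response (180
#' degrees by default), as required by the discrete Fourier phasor transform.
#'
#' @slot data numeric array, H x W x N, nonnegative intensities.
#' @slot angles numeric vector of N laser polarization angles in degrees,
#'   strictly increasing, uniformly spaced, within `[0, period)`.
#' @slot pixelSize pixel side length in micrometres.
#' @slot period angular period of the response in degrees (180).
#'
#' @seealso [polarizationStack()], [retrieveMaps()], [readStack()]
#' @export
setClass("PolarizationStack",
  representation(
    data = "array",
    angles = "numeric",
    pixelSize = "numeric",
    period = "numeric"
  ),
  prototype(pixelSize = 377 / 512, period = 180)
)

setValidity("PolarizationStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) {
    return("'data' must be a 3D array (H x W x N)")
  }
  if (d[3L] != length(object@angles)) {
    return("number of frames must equal number of angles")
  }
  msg <- checkAngleGrid(object@angles, object@period)
  if (!is.null(msg)) {
    return(msg)
  }
  if (anyNA(object@data) || any(!is.finite(object@data))) {
    return("'data' must be finite")
  }
  if (min(object@data) < 0) {
    return("'data' must be nonnegative")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0) {
    return("'pixelSize' must be a single positive number")
  }
  TRUE
})

#' MicroMaps: per-pixel fibril orientation and anisotropy maps
#'
#' The output of phasor retrieval: per-pixel maps of the mean in-plane fibril
#' orientation theta (degrees, axial, in `[0, 180)`) and the susceptibility
#' anisotropy gamma (dimensionless, `chi_zzz/chi_zxx`, nonnegative), with a
#' validity mask. Invalid pixels carry `NA` in both maps and are excluded
#' from all downstream statistics. Pixels with vanishing first harmonic
#' (gamma near 1) are retained but flagged orientation-degenerate: their
#' orientation is only defined modulo 90 degrees.
#'
#' @slot theta H x W orientation map in degrees, `NA` where invalid.
#' @slot gamma H x W anisotropy map, `NA` where invalid.
#' @slot valid H x W logical validity mask.
#' @slot degenerate H x W logical; orientation-degenerate pixels.
#' @slot meanIntensity H x W mean intensity over the polarization sweep.
#' @slot pixelSize pixel side length in micrometres.
#'
#' @seealso [retrieveMaps()], [analyzeSection()]
#' @export
setClass("MicroMaps",
  representation(
    theta = "matrix",
    gamma = "matrix",
    valid = "matrix",
    degenerate = "matrix",
    meanIntensity = "matrix",
    pixelSize = "numeric"
  )
)

setValidity("MicroMaps", function(object) {
  dims <- list(
    dim(object@theta), dim(object@gamma), dim(object@valid),
    dim(object@degenerate), dim(object@meanIntensity)
  )
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    return("all maps must share the same dimensions")
  }
  if (!is.logical(object@valid) || !is.logical(object@degenerate)) {
    return("'valid' and 'degenerate' must be logical")
  }
  ok <- object@valid
  th <- object@theta[ok]
  ga <- object@gamma[ok]
  if (anyNA(th) || anyNA(ga)) {
    return("valid pixels must carry finite theta and gamma")
  }
  if (length(th) && (min(th) < 0 || max(th) >= 180)) {
    return("valid theta values must lie in [0, 180)")
  }
  if (length(ga) && min(ga) < 0) {
    return("valid gamma values must be nonnegative")
  }
  if (!all(is.na(object@theta[!ok]))) {
    return("invalid pixels must carry NA theta")
  }
  TRUE
})

#' ReferenceCurve: phasor-space lookup curve for retrieval
#'
#' The locus of phasor coordinates `(g, s)` traced by the forward SHG model
#' as one parameter is swept: the theta curve sweeps the fibril orientation
#' over `[0, 180)` degrees in the high-anisotropy limit, the gamma curve
#' sweeps the anisotropy over `[0, 10]` on the fibril-aligned quarter-period
#' window. Retrieval maps measured phasor coordinates back to parameter
#' values through these curves.
#'
#' @slot param swept parameter values (degrees for theta, dimensionless for
#'   gamma), ascending.
#' @slot g,s phasor coordinates matching `param`.
#' @slot kind `"theta"` or `"gamma"`.
#'
#' @seealso [buildThetaReference()], [buildGammaReference()]
#' @export
setClass("ReferenceCurve",
  representation(param = "numeric", g = "numeric", s = "numeric",
                 kind = "character")
)

setValidity("ReferenceCurve", function(object) {
  n <- length(object@param)
  if (n < 2L) {
    return("reference curve needs at least 2 entries")
  }
  if (length(object@g) != n || length(object@s) != n) {
    return("'param', 'g' and 's' must have equal length")
  }
  if (is.unsorted(object@param, strictly = TRUE)) {
    return("'param' must be strictly increasing")
  }
  if (!object@kind %in% c("theta", "gamma")) {
    return("'kind' must be \"theta\" or \"gamma\"")
  }
  if (max(object@g^2 + object@s^2) > 1 + 1e-9) {
    return("phasor coordinates must lie within the unit disk")
  }
  TRUE
})

#' PhasorPlot: 2D histogram of per-pixel phasor coordinates
#'
#' Counts of valid pixels falling into a fixed square binning of the `(g, s)`
#' unit square `[-1, 1]^2`. Total counts equal the number of contributing
#' pixels.
#'
#' @slot counts bins x bins integer matrix (g along rows, s along columns).
#' @slot gBreaks,sBreaks bin break points.
#' @export
setClass("PhasorPlot",
  representation(counts = "matrix", gBreaks = "numeric", sBreaks = "numeric")
)

setValidity("PhasorPlot", function(object) {
  if (nrow(object@counts) != length(object@gBreaks) - 1L ||
      ncol(object@counts) != length(object@sBreaks) - 1L) {
    return("counts dimensions must match breaks")
  }
  if (any(object@counts < 0)) {
    return("counts must be nonnegative")
  }
  TRUE
})

#' ClusteringConfig: density-peak clustering parameters
#'
#' Holds the clustering cutoffs and discretization used throughout:
#' `thetaC` and `gammaC` are the per-axis cutoff distances from a cluster
#' center beyond which elements are discarded; `et` is the element threshold,
#' the minimum cluster occupancy expressed as a fraction of the analyzed
#' pixels (clusters at or below it are dropped); `dC` is the neighborhood
#' radius in the scaled feature space where theta is measured in units of
#' `thetaC` and gamma in units of `gammaC`; `thetaBin`/`gammaBin` set the
#' feature-grid quantization, chosen at least four times finer than the
#' cutoffs so the partition is unaffected.
#'
#' @slot thetaC orientation cutoff, degrees (default 5).
#' @slot gammaC anisotropy cutoff (default 0.2).
#' @slot et element threshold as a fraction in (0, 1) (default 0.01).
#' @slot dC neighborhood radius in scaled feature space (default 1).
#' @slot thetaBin orientation bin width, degrees (default 1).
#' @slot gammaBin anisotropy bin width (default 0.05).
#'
#' @seealso [clusteringConfig()], [densityPeakCluster()]
#' @export
setClass("ClusteringConfig",
  representation(
    thetaC = "numeric", gammaC = "numeric", et = "numeric",
    dC = "numeric", thetaBin = "numeric", gammaBin = "numeric"
  ),
  prototype(thetaC = 5, gammaC = 0.2, et = 0.01, dC = 1,
            thetaBin = 1, gammaBin = 0.05)
)

setValidity("ClusteringConfig", function(object) {
  vals <- c(object@thetaC, object@gammaC, object@et, object@dC,
            object@thetaBin, object@gammaBin)
  if (length(vals) != 6L || any(!is.finite(vals)) || any(vals <= 0)) {
    return("all clustering parameters must be single positive numbers")
  }
  if (object@et >= 1) {
    return("'et' must be a fraction in (0, 1)")
  }
  TRUE
})

#' FeatureGrid: quantized (theta, gamma) plane with pixel weights
#'
#' Occupied nodes of the quantized feature plane. Each node carries the
#' number of pixels that fall in its bin; `pixelNode` maps every input pixel
#' back to its node so cluster labels can be projected to the image. Nodes
#' are stored in a canonical theta-major, then gamma, order, which fixes all
#' tie-breaking in the clustering.
#'
#' @slot theta,gamma node (bin-center) coordinates, theta-major sorted.
#' @slot weight pixels per node; sums to the number of input pixels.
#' @slot pixelNode node index for each input pixel.
#' @slot nTotal total number of input pixels.
#' @export
setClass("FeatureGrid",
  representation(theta = "numeric", gamma = "numeric", weight = "numeric",
                 pixelNode = "integer", nTotal = "numeric")
)

setValidity("FeatureGrid", function(object) {
  n <- length(object@theta)
  if (length(object@gamma) != n || length(object@weight) != n) {
    return("node vectors must have equal length")
  }
  if (n && abs(sum(object@weight) - object@nTotal) > 1e-8) {
    return("node weights must sum to the total pixel count")
  }
  if (length(object@pixelNode) &&
      (min(object@pixelNode) < 1L || max(object@pixelNode) > n)) {
    return("'pixelNode' must index the nodes")
  }
  TRUE
})

#' ClusterModel: density-peak clustering result in (theta, gamma) space
#'
#' Cluster centers, per-node labels and per-cluster occupancies obtained by
#' maximum-density clustering of a [FeatureGrid], before or after pruning by
#' the per-axis cutoffs and the element threshold. Unassigned nodes carry
#' label `NA`.
#'
#' @slot centerNode node index of each cluster center.
#' @slot centerTheta,centerGamma center coordinates.
#' @slot nodeLabels integer cluster id per grid node (`NA` = unassigned).
#' @slot occupancies pixels per cluster (weights of its retained nodes).
#' @slot nTotal total analyzed pixels (the element-threshold reference).
#' @slot pruned logical; whether cutoff/threshold pruning has been applied.
#'
#' @seealso [densityPeakCluster()], [pruneClusters()], [clusterPixels()]
#' @export
setClass("ClusterModel",
  representation(
    centerNode = "integer", centerTheta = "numeric", centerGamma = "numeric",
    nodeLabels = "integer", occupancies = "numeric", nTotal = "numeric",
    pruned = "logical"
  )
)

setValidity("ClusterModel", function(object) {
  k <- length(object@centerNode)
  if (length(object@centerTheta) != k || length(object@centerGamma) != k ||
      length(object@occupancies) != k) {
    return("center vectors and occupancies must have equal length")
  }
  lab <- object@nodeLabels[!is.na(object@nodeLabels)]
  if (length(lab) && (min(lab) < 1L || max(lab) > k)) {
    return("node labels must index the centers")
  }
  TRUE
})

#' PParams: phasor-space descriptors of one region or ROI
#'
#' The three descriptors computed from a pruned [ClusterModel]: the number
#' of retained clusters, the cluster elements ratio (occupancy of each
#' cluster divided by the occupancy of the most populated one) and the
#' fibril entropy, the normalized Shannon entropy of the cluster occupancy
#' distribution (0 for a single cluster, 1 when every clustered element is
#' its own cluster).
#'
#' @slot nClusters number of retained clusters.
#' @slot cer cluster elements ratio vector, in `(0, 1]`, max equal to 1.
#' @slot entropy fibril entropy in `[0, 1]`.
#' @slot totalClustered total clustered elements (pruned pixels excluded).
#'
#' @seealso [pParams()], [fibrilEntropy()], [clusterElementsRatio()]
#' @export
setClass("PParams",
  representation(nClusters = "integer", cer = "numeric", entropy = "numeric",
                 totalClustered = "numeric")
)

setValidity("PParams", function(object) {
  if (object@nClusters > 0L) {
    if (length(object@cer) != object@nClusters) {
      return("'cer' must have one entry per cluster")
    }
    if (abs(max(object@cer) - 1) > 1e-12) {
      return("max CER must be 1")
    }
    if (object@entropy < -1e-12 || object@entropy > 1 + 1e-12) {
      return("entropy must lie in [0, 1]")
    }
  }
  TRUE
})

#' ROIGrid: non-overlapping square tiling of an image
#'
#' Sequential non-overlapping square tiles of side `roiSizeUm` micrometres
#' (converted to whole pixels), row-major from the image origin; partial
#' edge tiles are dropped.
#'
#' @slot roiSizeUm tile side in micrometres.
#' @slot roiSizePx tile side in pixels.
#' @slot rects data.frame with columns `row`, `col`, `height`, `width`
#'   (0-based, half-open pixel coordinates).
#' @slot imageShape image height and width in pixels.
#' @slot dim number of tile rows and columns.
#' @export
setClass("ROIGrid",
  representation(roiSizeUm = "numeric", roiSizePx = "integer",
                 rects = "data.frame", imageShape = "integer",
                 dim = "integer")
)

#' ROIAnalysis: per-ROI clustering descriptors over a section
#'
#' Results of running clustering and descriptor computation in every tile of
#' an [ROIGrid]: a per-ROI table and ROI-resolution maps of cluster count,
#' fibril entropy and the percentage of clusters at or below a CER
#' threshold. ROIs whose main (most populated) cluster holds fewer than
#' `minMainCluster` elements are flagged invalid and excluded from the
#' entropy threshold and the maps.
#'
#' @slot table data.frame, one row per ROI: `roi`, `row`, `col`,
#'   `nValidPixels`, `nClusters`, `entropy`, `cerPct`, `mainCluster`,
#'   `valid`.
#' @slot roiGrid the tiling used.
#' @slot cerThreshold CER threshold used for the `cerPct` column.
#' @slot minMainCluster validity threshold on the main-cluster occupancy.
#' @slot config the [ClusteringConfig] used.
#' @seealso [analyzeSection()], [entropyThreshold()], [segmentSection()]
#' @export
setClass("ROIAnalysis",
  representation(table = "data.frame", roiGrid = "ROIGrid",
                 cerThreshold = "numeric", minMainCluster = "numeric",
                 config = "ClusteringConfig")
)

#' SegmentationResult: entropy-threshold segmentation of a section
#'
#' Pixel mask obtained by back-projecting each valid ROI's entropy class
#' into the image plane: 0 = unclassified (invalid ROI or outside the
#' tiling), 1 = low entropy (at or below the threshold), 2 = high entropy
#' (strictly above).
#'
#' @slot mask integer H x W matrix with values 0, 1, 2.
#' @slot sTh entropy threshold used.
#' @slot entropyMap ROI-resolution entropy matrix (`NA` for invalid ROIs).
#' @slot roiGrid the tiling used.
#' @seealso [segmentSection()], [segmentationAccuracy()]
#' @export
setClass("SegmentationResult",
  representation(mask = "matrix", sTh = "numeric", entropyMap = "matrix",
                 roiGrid = "ROIGrid")
)
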