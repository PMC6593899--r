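#' Create a clustering configuration
#'
#' Constructor for [ClusteringConfig] with the standard tight-cutoff
#' defaults: orientation cutoff 5 degrees, anisotropy cutoff 0.2, element
#' threshold 1% of the analyzed pixels, neighborhood radius 1 in the scaled
#' feature space, and feature-grid bins of 1 degree and 0.05.
#'
#' @param thetaC orientation cutoff, degrees.
#' @param gammaC anisotropy cutoff.
#' @param et element threshold, fraction in (0, 1).
#' @param dC neighborhood radius in scaled feature space.
#' @param thetaBin,gammaBin feature-grid bin widths.
#' @return a [ClusteringConfig].
#' @examples
#' clusteringConfig(et = 0.005)
#' @export
clusteringConfig <- function(thetaC = 5, gammaC = 0.2, et = 0.01, dC = 1,
                             thetaBin = 1, gammaBin = 0.05) {
  new("ClusteringConfig", thetaC = thetaC, gammaC = gammaC, et = et,
      dC = dC, thetaBin = thetaBin, gammaBin = gammaBin)
}

#' Circular distance between two axial orientations
#'
#' Fibril orientation lives on a 180-degree-periodic circle; the distance
#' between two orientations is the smaller of the direct and wrap-around
#' separations, in `[0, 90]` degrees.
#'
#' @param a,b orientations in degrees (vectorized).
#' @return distance(s) in degrees.
#' @examples
#' circularThetaDistance(10, 170) # 20
#' @export
circularThetaDistance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Scaled distance in (theta, gamma) feature space
#'
#' Combines the two per-axis cutoffs into one metric: the circular
#' orientation distance in units of `thetaC` and the anisotropy difference
#' in units of `gammaC`, joined in quadrature. A distance of 1 along either
#' axis alone corresponds exactly to that axis's cutoff.
#'
#' @param p,q points as `c(theta, gamma)`, or matrices with two columns.
#' @param config a [ClusteringConfig].
#' @return scaled distance(s).
#' @export
scaledDistance <- function(p, q, config = clusteringConfig()) {
  p <- matrix(p, ncol = 2L)
  q <- matrix(q, ncol = 2L)
  sqrt((circularThetaDistance(p[, 1L], q[, 1L]) / config@thetaC)^2 +
         (abs(p[, 2L] - q[, 2L]) / config@gammaC)^2)
}

#' Quantize (theta, gamma) pixels onto a weighted feature grid
#'
#' Bins valid pixels on the quantized feature plane (bin widths from the
#' configuration) and records per-node pixel counts, making whole-section
#' clustering tractable: clustering then operates on at most a few thousand
#' weighted nodes rather than millions of raw pixels. Bins are at least four
#' times finer than the cutoffs, so the resulting partition matches raw-point
#' clustering (asserted against a brute-force oracle in the test suite).
#' Nodes are sorted theta-major then gamma, fixing all tie-breaks.
#'
#' @param theta,gamma numeric vectors of equal length (degrees, unitless).
#' @param config a [ClusteringConfig].
#' @return a [FeatureGrid].
#' @export
featureGrid <- function(theta, gamma, config = clusteringConfig()) {
  stopifnot(length(theta) == length(gamma))
  keep <- which(!is.na(theta) & !is.na(gamma))
  ti <- floor(theta[keep] / config@thetaBin)
  gi <- floor(gamma[keep] / config@gammaBin)
  key <- paste(ti, gi)
  uk <- unique(key)
  # canonical node order: theta-major, then gamma
  parts <- matrix(as.numeric(unlist(strsplit(uk, " ", fixed = TRUE))),
                  ncol = 2L, byrow = TRUE)
  o <- order(parts[, 1L], parts[, 2L])
  uk <- uk[o]
  parts <- parts[o, , drop = FALSE]
  nodeOf <- match(key, uk)
  w <- tabulate(nodeOf, nbins = length(uk))
  pixelNode <- rep(NA_integer_, length(theta))
  pixelNode[keep] <- nodeOf
  new("FeatureGrid",
    theta = (parts[, 1L] + 0.5) * config@thetaBin,
    gamma = (parts[, 2L] + 0.5) * config@gammaBin,
    weight = as.numeric(w),
    pixelNode = pixelNode,
    nTotal = as.numeric(length(keep))
  )
}

# pairwise scaled distances from nodes `ix` to all nodes (rows = ix)
nodeDistBlock <- function(grid, config, ix) {
  dt <- abs(outer(grid@theta[ix], grid@theta, "-")) %% 180
  dt <- pmin(dt, 180 - dt) / config@thetaC
  dg <- abs(outer(grid@gamma[ix], grid@gamma, "-")) / config@gammaC
  sqrt(dt^2 + dg^2)
}

#' Density-peak clustering of a weighted feature grid
#'
#' Maximum-density clustering in (theta, gamma) space. Each node's local
#' density is the total pixel weight within the scaled neighborhood radius
#' `dC` (cutoff kernel, self included); its separation is the scaled
#' distance to the nearest node of strictly higher density, with density
#' ties broken by the canonical node order and the global density maximum
#' assigned the largest pairwise distance. Cluster centers are nodes whose
#' separation exceeds `dC` and whose density exceeds the element-threshold
#' count `et * nTotal`; every other node inherits the label of its nearest
#' higher-density neighbor, walking down the density ranking. Nodes whose
#' inheritance chain reaches no center stay unassigned. The procedure is
#' fully deterministic.
#'
#' @param grid a [FeatureGrid] with at least one occupied node.
#' @param config a [ClusteringConfig].
#' @return an unpruned [ClusterModel]; apply [pruneClusters()] to enforce
#'   the per-axis cutoffs and the element threshold.
#' @seealso [pruneClusters()], [clusterPixels()]
#' @export
densityPeakCluster <- function(grid, config = clusteringConfig()) {
  n <- length(grid@theta)
  if (n == 0L) {
    stop("empty feature grid", call. = FALSE)
  }
  w <- grid@weight
  blk <- max(1L, floor(4e6 / n))
  rho <- numeric(n)
  maxDist <- 0
  for (st in seq(1L, n, by = blk)) {
    ix <- st:min(st + blk - 1L, n)
    d <- nodeDistBlock(grid, config, ix)
    rho[ix] <- as.vector((d < config@dC) %*% w)
    maxDist <- max(maxDist, max(d))
  }
  # total order: density descending, canonical node index ascending
  ord <- order(-rho, seq_len(n))
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  delta <- numeric(n)
  parent <- rep(NA_integer_, n)
  delta[ord[1L]] <- if (n == 1L) Inf else maxDist
  if (n > 1L) {
    for (st in seq(1L, n, by = blk)) {
      ix <- st:min(st + blk - 1L, n)
      d <- nodeDistBlock(grid, config, ix)
      # only nodes strictly earlier in the order may be parents
      mask <- outer(rank[ix], rank, ">")
      d[!mask] <- Inf
      keep <- rank[ix] > 1L
      if (any(keep)) {
        j <- max.col(-d[keep, , drop = FALSE], ties.method = "first")
        delta[ix[keep]] <- d[keep, , drop = FALSE][cbind(seq_along(j), j)]
        parent[ix[keep]] <- j
      }
    }
  }
  etCount <- config@et * grid@nTotal
  isCenter <- delta > config@dC & rho > etCount
  centers <- which(isCenter)
  labels <- rep(NA_integer_, n)
  labels[centers] <- seq_along(centers)
  for (i in ord) {
    if (!is.na(labels[i]) || is.na(parent[i])) next
    labels[i] <- labels[parent[i]]
  }
  occ <- vapply(seq_along(centers), function(k) {
    sum(w[which(labels == k)])
  }, 0)
  new("ClusterModel",
    centerNode = as.integer(centers),
    centerTheta = grid@theta[centers], centerGamma = grid@gamma[centers],
    nodeLabels = labels, occupancies = occ, nTotal = grid@nTotal,
    pruned = FALSE
  )
}

#' Prune a cluster model by per-axis cutoffs and the element threshold
#'
#' Enforces the two retention rules: elements farther than `thetaC`
#' (circular, per-axis) or `gammaC` (per-axis) from their cluster center are
#' unassigned, and clusters whose remaining occupancy is not strictly higher
#' than `et * nTotal` are removed entirely (their elements unassigned).
#' Occupancies are recomputed. Idempotent.
#'
#' @param model a [ClusterModel] from [densityPeakCluster()].
#' @param grid the [FeatureGrid] the model was built on.
#' @param config a [ClusteringConfig].
#' @return a pruned [ClusterModel] (empty clusters removed, ids compacted).
#' @export
pruneClusters <- function(model, grid, config = clusteringConfig()) {
  labels <- model@nodeLabels
  assigned <- which(!is.na(labels))
  if (length(assigned)) {
    lab <- labels[assigned]
    dt <- circularThetaDistance(grid@theta[assigned],
                                model@centerTheta[lab])
    dg <- abs(grid@gamma[assigned] - model@centerGamma[lab])
    drop <- dt > config@thetaC | dg > config@gammaC
    labels[assigned[drop]] <- NA_integer_
  }
  k <- length(model@centerNode)
  occ <- vapply(seq_len(k), function(i) {
    sum(grid@weight[which(labels == i)])
  }, 0)
  etCount <- config@et * model@nTotal
  keep <- which(occ > etCount)
  remap <- rep(NA_integer_, k)
  remap[keep] <- seq_along(keep)
  labels <- ifelse(is.na(labels), NA_integer_, remap[labels])
  new("ClusterModel",
    centerNode = model@centerNode[keep],
    centerTheta = model@centerTheta[keep],
    centerGamma = model@centerGamma[keep],
    nodeLabels = as.integer(labels), occupancies = occ[keep],
    nTotal = model@nTotal, pruned = TRUE
  )
}

#' Cluster (theta, gamma) pixels end to end
#'
#' Convenience wrapper: quantizes pixels onto the feature grid, runs
#' density-peak clustering and pruning, and projects cluster labels back to
#' the pixels.
#'
#' @param theta,gamma numeric vectors (NA allowed; such pixels are skipped).
#' @param config a [ClusteringConfig].
#' @return list with `model` (pruned [ClusterModel]), `grid`
#'   ([FeatureGrid]) and `pixelLabels` (integer per input pixel, `NA` when
#'   unassigned).
#' @examples
#' set.seed(1)
#' th <- c(rnorm(100, 30, 1), rnorm(100, 120, 1))
#' gm <- c(rnorm(100, 1.5, 0.03), rnorm(100, 2.5, 0.03))
#' res <- clusterPixels(th, gm)
#' res$model@occupancies
#' @export
clusterPixels <- function(theta, gamma, config = clusteringConfig()) {
  grid <- featureGrid(theta, gamma, config)
  model <- densityPeakCluster(grid, config)
  model <- pruneClusters(model, grid, config)
  pixelLabels <- rep(NA_integer_, length(theta))
  ok <- !is.na(grid@pixelNode)
  pixelLabels[ok] <- model@nodeLabels[grid@pixelNode[ok]]
  list(model = model, grid = grid, pixelLabels = pixelLabels)
}
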