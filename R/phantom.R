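#' Specify a two-region synthetic section phantom
#'
#' Describes a ground-truthed synthetic section with two regions of
#' contrasting collagen micro-architecture: an ordered, skin-like region
#' (few orientation modes, narrow anisotropy distribution centered near
#' 1.83) and a disordered, tumor-like region (near-uniform orientations,
#' broader anisotropy spread centered near 1.77). Each region is described
#' by a set of orientation modes (wrapped-normal on the 180-degree axial
#' circle; a mode with `sd = Inf` is uniform) and a truncated-normal
#' anisotropy distribution. Per-pixel intensity scales are log-normal, a
#' fraction of pixels is signal-free background, and rendering noise is
#' Poisson by default.
#'
#' The default geometry is a left/right split sized for a 2 x 4 tiling of
#' 150-micrometre ROIs at the standard pixel size (377/512 micrometres), so
#' region boundaries coincide with tile boundaries.
#'
#' @param imageShape height and width in pixels.
#' @param pixelSizeUm pixel side in micrometres.
#' @param geometry `"split"` (left = ordered, right = disordered) or
#'   `"disk"` (central disordered disk of half the image height in an
#'   ordered frame).
#' @param orderedThetaModes,disorderedThetaModes data.frames with columns
#'   `mean` (degrees), `sd` (circular SD, degrees; `Inf` = uniform) and
#'   `weight` (summing to 1 per region).
#' @param orderedGamma,disorderedGamma `c(mean, sd)` of the truncated-normal
#'   anisotropy distribution (truncated at 0).
#' @param backgroundFraction fraction of signal-free pixels. Only
#'   fibrillar collagen emits SHG, so a substantial part of a real section
#'   is dark; the default (0.15) also satisfies the validity estimator's
#'   assumption that the background fills at least the lowest intensity
#'   decile.
#' @param kSdLog log-normal SD of the per-pixel intensity scale.
#' @param noise `"poisson"`, `"gaussian"` or `"none"`.
#' @param peak Poisson mean count at the brightest sample of the noiseless
#'   stack (single detector-gain knob).
#' @param gaussianSd absolute Gaussian noise SD (when `noise = "gaussian"`).
#' @param darkCounts Poisson dark-count mean for background pixels
#'   (0 = ideal photon counting; background emits nothing).
#' @return a list of class `"PhantomSpec"`.
#' @seealso [makePhantom()], [renderStack()]
#' @export
phantomSpec <- function(imageShape = c(406L, 812L),
                        pixelSizeUm = 377 / 512,
                        geometry = c("split", "disk"),
                        orderedThetaModes = data.frame(
                          mean = c(30, 120), sd = c(4, 4),
                          weight = c(0.5, 0.5)
                        ),
                        disorderedThetaModes = data.frame(
                          mean = 0, sd = Inf, weight = 1
                        ),
                        orderedGamma = c(1.83, 0.10),
                        disorderedGamma = c(1.77, 0.35),
                        backgroundFraction = 0.15,
                        kSdLog = 0.2,
                        noise = c("poisson", "gaussian", "none"),
                        peak = 1000, gaussianSd = 0, darkCounts = 0) {
  geometry <- match.arg(geometry)
  noise <- match.arg(noise)
  for (m in list(orderedThetaModes, disorderedThetaModes)) {
    if (abs(sum(m$weight) - 1) > 1e-9 || any(m$sd < 0)) {
      stop("mode weights must sum to 1 and SDs be nonnegative",
           call. = FALSE)
    }
  }
  structure(
    list(
      imageShape = as.integer(imageShape), pixelSizeUm = pixelSizeUm,
      geometry = geometry,
      orderedThetaModes = orderedThetaModes,
      disorderedThetaModes = disorderedThetaModes,
      orderedGamma = orderedGamma, disorderedGamma = disorderedGamma,
      backgroundFraction = backgroundFraction, kSdLog = kSdLog,
      noise = noise, peak = peak, gaussianSd = gaussianSd,
      darkCounts = darkCounts
    ),
    class = "PhantomSpec"
  )
}

# sample n axial orientations from a mixture of wrapped normals
sampleTheta <- function(n, modes) {
  comp <- sample.int(nrow(modes), n, replace = TRUE, prob = modes$weight)
  out <- numeric(n)
  uni <- is.infinite(modes$sd[comp])
  out[uni] <- stats::runif(sum(uni), 0, 180)
  if (any(!uni)) {
    i <- which(!uni)
    out[i] <- (modes$mean[comp[i]] +
                 stats::rnorm(length(i), 0, modes$sd[comp[i]])) %% 180
  }
  out
}

# truncated normal at zero, by resampling
sampleGamma <- function(n, meanSd) {
  out <- stats::rnorm(n, meanSd[1L], meanSd[2L])
  while (any(bad <- out < 0)) {
    out[bad] <- stats::rnorm(sum(bad), meanSd[1L], meanSd[2L])
  }
  out
}

#' Generate a ground-truthed phantom section
#'
#' Samples per-pixel ground-truth orientation, anisotropy and intensity
#' scale from the region populations of a [phantomSpec()], flags background
#' pixels, and returns the truth as [MicroMaps] together with the binary
#' region reference mask (`TRUE` = disordered region) and the per-pixel
#' scale map. Reproducible under `seed`.
#'
#' @param spec a `"PhantomSpec"`.
#' @param seed integer seed.
#' @return list with `truth` ([MicroMaps]), `regionMask` (logical matrix),
#'   `k` (numeric matrix) and `spec`.
#' @export
makePhantom <- function(spec = phantomSpec(), seed = 1L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  h <- spec$imageShape[1L]
  w <- spec$imageShape[2L]
  if (h < 2L || w < 2L) {
    stop("degenerate phantom geometry", call. = FALSE)
  }
  set.seed(childSeed(seed, 1L))
  if (spec$geometry == "split") {
    regionMask <- matrix(rep(seq_len(w) > w / 2, each = h), h, w)
  } else {
    cy <- (h + 1) / 2
    cx <- (w + 1) / 2
    rad <- h / 4
    regionMask <- outer(seq_len(h), seq_len(w), function(r, c) {
      (r - cy)^2 + (c - cx)^2 <= rad^2
    })
  }
  if (!any(regionMask) || all(regionMask)) {
    stop("degenerate phantom geometry: one region is empty", call. = FALSE)
  }
  nDis <- sum(regionMask)
  nOrd <- h * w - nDis
  theta <- gamma <- matrix(NA_real_, h, w)
  theta[!regionMask] <- sampleTheta(nOrd, spec$orderedThetaModes)
  theta[regionMask] <- sampleTheta(nDis, spec$disorderedThetaModes)
  gamma[!regionMask] <- sampleGamma(nOrd, spec$orderedGamma)
  gamma[regionMask] <- sampleGamma(nDis, spec$disorderedGamma)
  k <- matrix(stats::rlnorm(h * w, 0, spec$kSdLog), h, w)
  valid <- matrix(TRUE, h, w)
  if (spec$backgroundFraction > 0) {
    bg <- sample.int(h * w, round(spec$backgroundFraction * h * w))
    valid[bg] <- FALSE
    theta[bg] <- NA_real_
    gamma[bg] <- NA_real_
    k[bg] <- 0
  }
  truth <- new("MicroMaps",
    theta = theta, gamma = gamma, valid = valid,
    degenerate = matrix(FALSE, h, w),
    meanIntensity = k, pixelSize = spec$pixelSizeUm
  )
  list(truth = truth, regionMask = regionMask, k = k, spec = spec)
}

#' Render a phantom into a polarization stack
#'
#' Drives the forward SHG model per pixel over the acquisition angle grid
#' and applies the detection noise: Poisson counts under a single global
#' gain scaling the brightest noiseless sample to `peak` expected counts
#' (background pixels emit dark counts only), or additive Gaussian noise,
#' or none. A noiseless render followed by phasor retrieval reproduces the
#' ground truth within the retrieval tolerances.
#'
#' @param phantom result of [makePhantom()].
#' @param angles acquisition angle grid, degrees.
#' @param noise noise model override; defaults to the phantom spec's.
#' @param seed integer seed for the noise draw.
#' @return a [PolarizationStack].
#' @export
renderStack <- function(phantom, angles = defaultAngles(), noise = NULL,
                        seed = 1L) {
  stopIfBadGrid(angles)
  spec <- phantom$spec
  if (is.null(noise)) {
    noise <- spec$noise
  }
  truth <- phantom$truth
  h <- nrow(truth@theta)
  w <- ncol(truth@theta)
  nA <- length(angles)
  th <- as.vector(truth@theta)
  gm <- as.vector(truth@gamma)
  kk <- as.vector(phantom$k)
  ok <- as.vector(truth@valid)
  stack <- matrix(0, h * w, nA)
  if (any(ok)) {
    d <- outer(th[ok], angles, function(a, b) (b - a) * pi / 180)
    stack[ok, ] <- kk[ok] *
      (sin(2 * d)^2 + (sin(d)^2 + gm[ok] * cos(d)^2)^2)
  }
  set.seed(childSeed(seed, 2L))
  if (noise == "poisson") {
    m <- max(stack)
    scale <- if (m > 0) spec$peak / m else 1
    lam <- stack * scale
    lam[!ok, ] <- spec$darkCounts
    stack <- matrix(as.numeric(stats::rpois(length(lam), lam)), h * w, nA)
  } else if (noise == "gaussian") {
    stack <- pmax(stack + stats::rnorm(length(stack), 0, spec$gaussianSd),
                  0)
  }
  new("PolarizationStack",
    data = array(stack, c(h, w, nA)), angles = angles,
    pixelSize = spec$pixelSizeUm, period = 180
  )
}
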