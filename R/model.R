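#' Microscopic SHG polarization response
#'
#' Forward model for the SHG intensity of collagen fibrils as a function of
#' the laser polarization angle. With `delta = thetaL - thetaF` the relative
#' angle between the laser polarization and the mean in-plane fibril
#' orientation, the response is
#' \deqn{I(\theta_L) = k\{\sin^2(2\Delta) + [\sin^2\Delta +
#'   \gamma\cos^2\Delta]^2\}}
#' where `gamma` is the susceptibility anisotropy (the ratio of the two
#' independent second-order susceptibility tensor entries under cylindrical
#' and Kleinman symmetry) and `k` an arbitrary intensity scale. The response
#' is pi-periodic in both angles and nonnegative for `gamma >= 0`.
#'
#' Over one period the response expands exactly into three harmonics,
#' `d + h1 cos(2 delta) + h2 cos(4 delta)` with `h1 = (gamma^2 - 1)/2`; the
#' first harmonic vanishes at `gamma = 1`, where the orientation becomes
#' degenerate (defined only modulo 90 degrees).
#'
#' @param thetaL laser polarization angle(s), degrees. Vectorized.
#' @param thetaF mean fibril orientation, degrees.
#' @param gamma susceptibility anisotropy, `>= 0`.
#' @param k intensity scale, `> 0`.
#' @return nonnegative intensity, same length as `thetaL`.
#' @examples
#' shgIntensity(0, thetaF = 0, gamma = 2) # bracket = gamma^2 = 4
#' shgIntensity(90, thetaF = 0, gamma = 5) # bracket = 1
#' @export
shgIntensity <- function(thetaL, thetaF, gamma, k = 1) {
  if (length(gamma) != 1L || !is.finite(gamma) || gamma < 0) {
    stop("'gamma' must be a single nonnegative number", call. = FALSE)
  }
  if (length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("'k' must be a single positive number", call. = FALSE)
  }
  d <- (thetaL - thetaF) * pi / 180
  k * (sin(2 * d)^2 + (sin(d)^2 + gamma * cos(d)^2)^2)
}

# harmonic decomposition of the response over one period (internal; used by
# reference-curve construction and by tests of the closed form)
shgHarmonics <- function(gamma, k = 1) {
  a <- (1 + gamma) / 2
  b <- (gamma - 1) / 2
  c(
    dc = k * (1 / 2 + a^2 + b^2 / 2),
    h1 = k * (gamma^2 - 1) / 2,
    h2 = k * ((gamma - 1)^2 - 4) / 8
  )
}

#' Simulate a per-pixel polarization response
#'
#' Renders the forward SHG model over an acquisition angle grid, optionally
#' corrupted by noise. Gaussian noise adds i.i.d. `N(0, sd^2)` counts
#' (clamped at zero); Poisson noise draws photon counts with the mean scaled
#' so that the response maximum equals `peak` expected counts, emulating a
#' photon-counting detector with a single intuitive knob.
#'
#' @param thetaF fibril orientation, degrees.
#' @param gamma susceptibility anisotropy, `>= 0`.
#' @param k intensity scale.
#' @param angles polarization angle grid, degrees (uniform; one period).
#' @param noise one of `"none"`, `"gaussian"`, `"poisson"`.
#' @param sd Gaussian noise standard deviation (intensity units).
#' @param peak Poisson mean photon count at the response maximum.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of intensities, one per angle.
#' @examples
#' r <- simulateResponse(30, gamma = 2)
#' angles <- defaultAngles()
#' angles[which.max(r)] # response peaks at the fibril orientation
#' @export
simulateResponse <- function(thetaF, gamma, k = 1, angles = defaultAngles(),
                             noise = c("none", "gaussian", "poisson"),
                             sd = 0, peak = 1000, seed = NULL) {
  noise <- match.arg(noise)
  if (length(angles) == 0L) {
    stop("empty angle grid", call. = FALSE)
  }
  stopIfBadGrid(angles)
  resp <- shgIntensity(angles, thetaF, gamma, k)
  if (noise == "none") {
    return(resp)
  }
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  }
  if (noise == "gaussian") {
    pmax(resp + stats::rnorm(length(resp), sd = sd), 0)
  } else {
    m <- max(resp)
    if (m <= 0) {
      return(numeric(length(resp)))
    }
    as.numeric(stats::rpois(length(resp), resp / m * peak))
  }
}
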