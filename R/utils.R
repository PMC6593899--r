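# internal helpers shared across modules

# validate a polarization angle grid; NULL if fine, message otherwise
checkAngleGrid <- function(angles, period = 180) {
  if (length(angles) < 2L) {
    return("need at least 2 polarization angles")
  }
  if (anyNA(angles) || any(!is.finite(angles))) {
    return("angles must be finite")
  }
  if (is.unsorted(angles, strictly = TRUE)) {
    return("angles must be strictly increasing")
  }
  if (min(angles) < 0 || max(angles) >= period) {
    return(sprintf("angles must lie within [0, %g)", period))
  }
  steps <- diff(angles)
  if (max(steps) - min(steps) > 1e-9 * max(steps)) {
    return("angles must be uniformly spaced (required by the DFT phasor)")
  }
  NULL
}

stopIfBadGrid <- function(angles, period = 180) {
  msg <- checkAngleGrid(angles, period)
  if (!is.null(msg)) {
    stop(msg, call. = FALSE)
  }
  invisible(angles)
}

#' Default polarization angle grid
#'
#' 36 angles from 0 to 175 degrees in 5-degree steps: one full period of the
#' pi-periodic SHG polarization response at the granularity of a half-wave
#' plate swept in 5-degree steps. The DFT phasor requires exactly an integer
#' number of periods, so the acquisition sweep is collapsed onto a single
#' period.
#'
#' @param n number of angles.
#' @param period angular period in degrees.
#' @return numeric vector of angles in degrees.
#' @examples
#' defaultAngles()
#' @export
defaultAngles <- function(n = 36L, period = 180) {
  seq(0, period - period / n, length.out = n)
}

# deterministic child seeds below 2^31 derived from one user seed
childSeed <- function(seed, index) {
  (as.integer(seed) * 7919L + as.integer(index) * 104729L) %% 2147483123L
}
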