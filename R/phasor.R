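#' DFT phasor transform of a periodic intensity signal
#'
#' Maps a sampled periodic, nonnegative signal to its normalized Fourier
#' coordinates at harmonic `m`:
#' \deqn{g = \sum_n I_n \cos(2\pi m n/N) / \sum_n I_n, \quad
#'       s = \sum_n I_n \sin(2\pi m n/N) / \sum_n I_n.}
#' For any nonnegative signal the point `(g, s)` lies within the unit disk.
#'
#' @param signal nonnegative intensity vector sampled uniformly over one
#'   period, length at least `2 * harmonic + 1`, not all zero.
#' @param harmonic positive integer harmonic index.
#' @return named numeric vector `c(g = , s = )`.
#' @examples
#' n <- 0:7
#' dftPhasor(1 + cos(2 * pi * n / 8)) # (0.5, 0)
#' @export
dftPhasor <- function(signal, harmonic = 1L) {
  n <- length(signal)
  if (harmonic < 1L || n < 2L * harmonic + 1L) {
    stop("signal too short for requested harmonic", call. = FALSE)
  }
  if (anyNA(signal) || min(signal) < 0) {
    stop("signal must be nonnegative", call. = FALSE)
  }
  tot <- sum(signal)
  if (tot <= 0) {
    stop("all-zero signal has no defined phasor", call. = FALSE)
  }
  idx <- 2 * pi * harmonic * (seq_len(n) - 1) / n
  c(g = sum(signal * cos(idx)) / tot, s = sum(signal * sin(idx)) / tot)
}

#' Build the orientation (theta) reference curve
#'
#' Sweeps the fibril orientation over `[0, 180)` degrees in the
#' high-anisotropy limit of the forward model — where the response reduces
#' to the `cos^4(delta)` envelope after scale normalization — and records
#' the first-harmonic phasor of each response. The curve traces a closed
#' loop as the orientation advances by 180 degrees; the phasor phase is
#' linear in the orientation, which makes the curve an exact lookup from
#' phase to orientation.
#'
#' @param angles acquisition angle grid, degrees.
#' @param thetaSamples number of swept orientations.
#' @return a [ReferenceCurve] of kind `"theta"`.
#' @export
buildThetaReference <- function(angles = defaultAngles(),
                                thetaSamples = 721L) {
  stopIfBadGrid(angles)
  if (thetaSamples < 2L) {
    stop("'thetaSamples' must be at least 2", call. = FALSE)
  }
  thetas <- seq(0, 180 - 180 / thetaSamples, length.out = thetaSamples)
  coords <- vapply(thetas, function(th) {
    d <- (angles - th) * pi / 180
    dftPhasor(cos(d)^4)
  }, c(g = 0, s = 0))
  new("ReferenceCurve", param = thetas, g = coords["g", ],
      s = coords["s", ], kind = "theta")
}

#' Build the anisotropy (gamma) reference curve
#'
#' For each anisotropy value on a grid over `[0, 10]`, samples the noiseless
#' forward response on the fibril-aligned quarter-period window
#' `delta in [0, 90)` degrees and records the first-harmonic phasor of the
#' windowed signal. The intensity scale cancels in the normalization, so the
#' curve depends on the anisotropy alone; it is injective on the default
#' 0.01-step grid, giving a nearest-neighbour lookup from windowed phasor
#' coordinates to anisotropy.
#'
#' @param gammaGrid ascending anisotropy grid within `[0, 10]`.
#' @param windowSamples samples across the 90-degree window, at least 4.
#' @return a [ReferenceCurve] of kind `"gamma"`.
#' @export
buildGammaReference <- function(gammaGrid = seq(0, 10, by = 0.01),
                                windowSamples = 16L) {
  if (windowSamples < 4L) {
    stop("'windowSamples' must be at least 4", call. = FALSE)
  }
  if (is.unsorted(gammaGrid, strictly = TRUE) ||
      min(gammaGrid) < 0 || max(gammaGrid) > 10) {
    stop("'gammaGrid' must be ascending within [0, 10]", call. = FALSE)
  }
  win <- seq(0, 90 - 90 / windowSamples, length.out = windowSamples)
  coords <- vapply(gammaGrid, function(gm) {
    dftPhasor(shgIntensity(win, 0, gm))
  }, c(g = 0, s = 0))
  new("ReferenceCurve", param = gammaGrid, g = coords["g", ],
      s = coords["s", ], kind = "gamma")
}

# orientation from first-harmonic phase via the theta reference curve:
# the curve phase is monotone in the orientation over one turn, so lookup is
# a circular linear interpolation (vectorized over phases, radians)
thetaFromPhase <- function(phase, thetaRef) {
  refPhase <- atan2(thetaRef@s, thetaRef@g)
  refPhase <- refPhase %% (2 * pi)
  o <- order(refPhase)
  rp <- refPhase[o]
  rt <- thetaRef@param[o]
  # unwrap theta alongside the sorted phase so interpolation stays circular
  rt <- (rt - rt[1L]) %% 180 + rt[1L]
  rt <- rt + cumsum(c(0, diff(rt) < -90) * 180)
  q <- phase %% (2 * pi)
  out <- stats::approx(
    x = c(rp, rp[1L] + 2 * pi), y = c(rt, rt[1L] + 180),
    xout = q, rule = 2
  )$y
  out %% 180
}

# resample a periodic response (matrix P x N on `angles`) onto the
# fibril-aligned window delta in [0, 90), W samples, by linear interpolation
# with periodic extension; thetaCand is per-row (length P)
alignWindow <- function(sig, angles, thetaCand, windowSamples = 16L) {
  nA <- length(angles)
  step <- angles[2L] - angles[1L]
  win <- seq(0, 90 - 90 / windowSamples, length.out = windowSamples)
  ang <- outer(thetaCand, win, "+") %% 180
  pos <- (ang - angles[1L]) / step
  i0 <- floor(pos)
  fr <- pos - i0
  i0 <- i0 %% nA
  i1 <- (i0 + 1L) %% nA
  p <- nrow(sig)
  rows <- rep.int(seq_len(p), windowSamples)
  w0 <- matrix(sig[cbind(rows, as.vector(i0) + 1L)], p, windowSamples)
  w1 <- matrix(sig[cbind(rows, as.vector(i1) + 1L)], p, windowSamples)
  (1 - fr) * w0 + fr * w1
}

# first-harmonic phasor of each row of a matrix (rows = signals)
rowPhasor <- function(mat, harmonic = 1L) {
  n <- ncol(mat)
  idx <- 2 * pi * harmonic * (seq_len(n) - 1) / n
  tot <- rowSums(mat)
  list(g = as.vector(mat %*% cos(idx)) / tot,
       s = as.vector(mat %*% sin(idx)) / tot)
}

# nearest-neighbour gamma lookup in (g, s), chunked to bound memory
gammaLookup <- function(g, s, gammaRef, chunk = 4096L) {
  out <- numeric(length(g))
  rg <- gammaRef@g
  rs <- gammaRef@s
  for (st in seq(1L, length(g), by = chunk)) {
    en <- min(st + chunk - 1L, length(g))
    d2 <- outer(g[st:en], rg, "-")^2 + outer(s[st:en], rs, "-")^2
    out[st:en] <- gammaRef@param[max.col(-d2, ties.method = "first")]
  }
  out
}

# vectorized retrieval core. sig: P x N nonnegative matrix (P pixels).
# Returns per-pixel theta, gamma, residual, validity, degeneracy flags and
# the phasor coordinates feeding the theta- and gamma- phasor plots.
retrieveCore <- function(sig, angles, thetaRef, gammaRef,
                         ampTol = 1e-7, windowSamples = 16L) {
  p <- nrow(sig)
  n <- ncol(sig)
  tot <- rowSums(sig)
  ph1 <- rowPhasor(sig, 1L)
  ph2 <- rowPhasor(sig, 2L)
  g1 <- ph1$g
  s1 <- ph1$s
  amp1 <- sqrt(g1^2 + s1^2)
  amp2 <- sqrt(ph2$g^2 + ph2$s^2)
  valid <- tot > 0 & (amp1 >= ampTol | amp2 >= ampTol)
  degenerate <- valid & amp1 < ampTol

  theta <- rep(NA_real_, p)
  gamma <- rep(NA_real_, p)
  residual <- rep(NA_real_, p)
  wg <- rep(NA_real_, p)
  ws <- rep(NA_real_, p)
  if (!any(valid)) {
    return(list(theta = theta, gamma = gamma, residual = residual,
                valid = valid, degenerate = degenerate,
                g1 = g1, s1 = s1, wg = wg, ws = ws))
  }

  iv <- which(valid & !degenerate)
  idg <- which(degenerate)
  thCand <- rep(NA_real_, p)
  if (length(iv)) {
    thCand[iv] <- thetaFromPhase(atan2(s1[iv], g1[iv]), thetaRef)
  }
  if (length(idg)) {
    # gamma near 1: first harmonic vanishes; take orientation (modulo 90)
    # from the second-harmonic phase, whose coefficient is negative there
    ph <- atan2(ph2$s[idg], ph2$g[idg])
    thCand[idg] <- ((ph - pi) / 4 * 180 / pi) %% 90
  }

  # candidate search: for each orientation offset, resample the window,
  # look the anisotropy up on the reference curve, refine it locally by
  # least squares (under noise the nearest-curve coordinate can sit a few
  # grid steps off, which would distort the disambiguation residual), and
  # keep the lowest-residual solution per pixel
  candidateSearch <- function(sigV, thA, offsets) {
    best <- NULL
    for (off in offsets) {
      th <- (thA + off) %% 180
      wsig <- alignWindow(sigV, angles, th, windowSamples)
      wph <- rowPhasor(wsig, 1L)
      gm0 <- gammaLookup(wph$g, wph$s, gammaRef)
      dmat <- (outer(th, angles, function(a, b) b - a)) * pi / 180
      s2 <- sin(dmat)^2
      c2 <- cos(dmat)^2
      s22 <- sin(2 * dmat)^2
      gmBest <- gm0
      rssBest <- rep(Inf, length(gm0))
      for (dg in c(seq(-0.08, 0.08, by = 0.02),
                   -0.15, 0.15, -0.25, 0.25)) {
        gm <- pmax(gm0 + dg, 0)
        f <- s22 + (s2 + gm * c2)^2
        kh <- rowSums(sigV * f) / rowSums(f * f)
        rss <- rowSums((sigV - kh * f)^2)
        take <- rss < rssBest
        gmBest[take] <- gm[take]
        rssBest[take] <- rss[take]
      }
      cand <- list(th = th, gm = gmBest, rss = rssBest,
                   wg = wph$g, ws = wph$s)
      if (is.null(best)) {
        best <- cand
      } else {
        take <- cand$rss < best$rss
        for (nm in names(best)) {
          best[[nm]][take] <- cand[[nm]][take]
        }
      }
    }
    best
  }

  # a weak first harmonic (gamma near 1) carries a noisy phase, so its
  # orientation candidate gets a local search of its own
  relA <- amp1 / (amp1 + amp2)
  iAll <- which(valid)
  groups <- list(
    list(ix = iAll[relA[iAll] >= 0.5 | degenerate[iAll]],
         offsets = c(0, 90)),
    list(ix = iAll[relA[iAll] < 0.5 & !degenerate[iAll]],
         offsets = c(-4, -2, 0, 2, 4, 86, 88, 90, 92, 94))
  )
  for (grp in groups) {
    if (length(grp$ix) == 0L) next
    best <- candidateSearch(sig[grp$ix, , drop = FALSE],
                            thCand[grp$ix], grp$offsets)
    theta[grp$ix] <- best$th
    gamma[grp$ix] <- best$gm
    residual[grp$ix] <- best$rss
    wg[grp$ix] <- best$wg
    ws[grp$ix] <- best$ws
  }
  # degenerate pixels: report the modulo-90 representative
  theta[idg] <- theta[idg] %% 90
  list(theta = theta, gamma = gamma, residual = residual,
       valid = valid, degenerate = degenerate,
       g1 = g1, s1 = s1, wg = wg, ws = ws)
}

#' Retrieve orientation and anisotropy from one pixel response
#'
#' Inverts the forward SHG model for a single polarization response via the
#' phasor transform: the orientation candidate is read from the
#' first-harmonic phase through the theta reference curve; the response is
#' then resampled onto the fibril-aligned quarter-period window and the
#' anisotropy read off the gamma reference curve by nearest phasor
#' coordinate. The two candidate solutions arising from the sign degeneracy
#' of the first harmonic (orientation versus orientation + 90 degrees) are
#' disambiguated by the smaller sum-of-squares residual against the forward
#' model.
#'
#' @param signal intensity vector over `angles`.
#' @param angles acquisition angle grid, degrees.
#' @param thetaRef,gammaRef reference curves; built with defaults when
#'   omitted.
#' @return list with `theta` (degrees in `[0, 180)`), `gamma`, `residual`,
#'   `valid` and `degenerate`. Degenerate pixels (vanishing first harmonic,
#'   anisotropy near 1) report the orientation modulo 90 degrees.
#' @examples
#' sig <- simulateResponse(30, gamma = 2)
#' retrievePixel(sig)[c("theta", "gamma")]
#' @export
retrievePixel <- function(signal, angles = defaultAngles(),
                          thetaRef = NULL, gammaRef = NULL) {
  stopIfBadGrid(angles)
  if (length(signal) != length(angles)) {
    stop("signal length must match the angle grid", call. = FALSE)
  }
  if (is.null(thetaRef)) {
    thetaRef <- buildThetaReference(angles)
  }
  if (is.null(gammaRef)) {
    gammaRef <- buildGammaReference()
  }
  r <- retrieveCore(matrix(signal, nrow = 1L), angles, thetaRef, gammaRef)
  list(theta = r$theta, gamma = r$gamma, residual = r$residual,
       valid = r$valid, degenerate = r$degenerate)
}

# 2D histogram of phasor coordinates over [-1, 1]^2
makePhasorPlot <- function(g, s, bins = 128L) {
  brk <- seq(-1, 1, length.out = bins + 1L)
  gi <- pmin(pmax(findInterval(g, brk, rightmost.closed = TRUE), 1L), bins)
  si <- pmin(pmax(findInterval(s, brk, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  tb <- table(factor(gi, levels = seq_len(bins)),
              factor(si, levels = seq_len(bins)))
  counts[] <- as.integer(tb)
  new("PhasorPlot", counts = counts, gBreaks = brk, sBreaks = brk)
}

#' Retrieve whole-image orientation and anisotropy maps
#'
#' Applies phasor retrieval to every pixel of a [PolarizationStack] whose
#' mean intensity exceeds the validity threshold, producing [MicroMaps] and
#' the two accumulated phasor plots (the theta plot from the first harmonic
#' of the full response, the gamma plot from the first harmonic of the
#' fibril-aligned window). By default the threshold is estimated as the
#' background mean plus three background standard deviations, with the
#' background taken from the lowest-intensity decile; pass
#' `intensityThreshold` for an absolute override.
#'
#' @param stack a [PolarizationStack].
#' @param intensityThreshold absolute mean-intensity threshold, or `NULL`
#'   for the background-based estimate.
#' @param thetaRef,gammaRef reference curves; built with defaults when
#'   omitted.
#' @param bins phasor-plot bin count per axis.
#' @param chunkSize pixels processed per block (memory bound).
#' @return list with elements `maps` ([MicroMaps]), `thetaPlot` and
#'   `gammaPlot` ([PhasorPlot]), and `residual` (H x W matrix).
#' @export
retrieveMaps <- function(stack, intensityThreshold = NULL,
                         thetaRef = NULL, gammaRef = NULL, bins = 128L,
                         chunkSize = 16384L) {
  stopifnot(is(stack, "PolarizationStack"))
  angles <- stack@angles
  if (is.null(thetaRef)) {
    thetaRef <- buildThetaReference(angles)
  }
  if (is.null(gammaRef)) {
    gammaRef <- buildGammaReference()
  }
  d <- dim(stack@data)
  h <- d[1L]
  w <- d[2L]
  nA <- d[3L]
  p <- h * w
  sig <- matrix(stack@data, nrow = p, ncol = nA)
  meanI <- rowMeans(sig)
  if (is.null(intensityThreshold)) {
    intensityThreshold <- backgroundThreshold(meanI)
  }
  keep <- which(meanI >= intensityThreshold & meanI > 0)

  theta <- rep(NA_real_, p)
  gamma <- rep(NA_real_, p)
  residual <- rep(NA_real_, p)
  valid <- rep(FALSE, p)
  degen <- rep(FALSE, p)
  g1 <- s1 <- wg <- ws <- numeric(0)
  starts <- if (length(keep)) seq(1L, length(keep), by = chunkSize) else integer(0)
  for (st in starts) {
    en <- min(st + chunkSize - 1L, length(keep))
    ix <- keep[st:en]
    r <- retrieveCore(sig[ix, , drop = FALSE], angles, thetaRef, gammaRef)
    theta[ix] <- r$theta
    gamma[ix] <- r$gamma
    residual[ix] <- r$residual
    valid[ix] <- r$valid
    degen[ix] <- r$degenerate
    ok <- r$valid
    g1 <- c(g1, r$g1[ok])
    s1 <- c(s1, r$s1[ok])
    wg <- c(wg, r$wg[ok])
    ws <- c(ws, r$ws[ok])
  }
  theta[!valid] <- NA_real_
  gamma[!valid] <- NA_real_
  maps <- new("MicroMaps",
    theta = matrix(theta, h, w), gamma = matrix(gamma, h, w),
    valid = matrix(valid, h, w), degenerate = matrix(degen, h, w),
    meanIntensity = matrix(meanI, h, w), pixelSize = stack@pixelSize
  )
  list(
    maps = maps,
    thetaPlot = makePhasorPlot(g1, s1, bins),
    gammaPlot = makePhasorPlot(wg, ws, bins),
    residual = matrix(residual, h, w)
  )
}

# background-based validity threshold: mean + 3 SD of the lowest-intensity
# decile (ties at the threshold count as valid, so a uniform noiseless image
# keeps all pixels)
backgroundThreshold <- function(meanI) {
  q <- stats::quantile(meanI, 0.1, names = FALSE)
  bg <- meanI[meanI <= q]
  s <- stats::sd(bg)
  if (!is.finite(s)) {
    s <- 0
  }
  mean(bg) + 3 * s
}
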