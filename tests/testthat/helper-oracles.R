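# Independent oracles used to validate the implementation.

# forward model, written out independently of shgIntensity
oracleModel <- function(thetaL, thetaF, gamma, k = 1) {
  delta <- (thetaL - thetaF) / 180 * pi
  bracket <- sin(delta)^2 + gamma * cos(delta)^2
  k * (sin(2 * delta)^2 + bracket^2)
}

# brute-force retrieval oracle: exhaustive grid search over (thetaF, gamma)
# minimizing the sum of squares against the forward model with the scale
# profiled out analytically
oracleRetrieve <- function(signal, angles, thetaStep = 0.5,
                           gammaStep = 0.02, gammaMax = 8) {
  thetas <- seq(0, 180 - thetaStep, by = thetaStep)
  gammas <- seq(0, gammaMax, by = gammaStep)
  best <- c(theta = NA, gamma = NA, rss = Inf)
  for (th in thetas) {
    for (gm in gammas) {
      f <- oracleModel(angles, th, gm)
      kh <- sum(signal * f) / sum(f * f)
      rss <- sum((signal - kh * f)^2)
      if (rss < best["rss"]) {
        best <- c(theta = th, gamma = gm, rss = rss)
      }
    }
  }
  best
}

# brute-force density-peak clustering on raw points (weight 1 each),
# written with explicit loops, following the declared rules:
#   rho_i = #points within dC (scaled metric, self included)
#   order: rho descending, ties by canonical (theta-major) point order
#   delta_i = distance to nearest point earlier in the order
#   centers: delta > dC and rho > et * n
#   assignment: inherit from the nearest earlier point, walking the order
#   prune: per-axis cutoffs from the center, then occupancy > et * n
oracleDPC <- function(theta, gamma, thetaC = 5, gammaC = 0.2, et = 0.01,
                      dC = 1) {
  o <- order(theta, gamma)
  th <- theta[o]
  gm <- gamma[o]
  n <- length(th)
  dist <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dt <- abs(th[i] - th[j])
      dt <- min(dt, 180 - dt) / thetaC
      dg <- abs(gm[i] - gm[j]) / gammaC
      dist[i, j] <- sqrt(dt^2 + dg^2)
    }
  }
  rho <- numeric(n)
  for (i in seq_len(n)) rho[i] <- sum(dist[i, ] < dC)
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  parent <- rep(NA_integer_, n)
  delta[ord[1L]] <- if (n == 1L) Inf else max(dist)
  if (n > 1L) {
    for (p in 2:n) {
      i <- ord[p]
      prev <- ord[seq_len(p - 1L)]
      j <- prev[which.min(dist[i, prev])]
      delta[i] <- dist[i, j]
      parent[i] <- j
    }
  }
  centers <- which(delta > dC & rho > et * n)
  labels <- rep(NA_integer_, n)
  labels[centers] <- seq_along(centers)
  for (p in seq_len(n)) {
    i <- ord[p]
    if (is.na(labels[i]) && !is.na(parent[i])) {
      labels[i] <- labels[parent[i]]
    }
  }
  for (i in seq_len(n)) {
    if (is.na(labels[i])) next
    ci <- centers[labels[i]]
    dt <- abs(th[i] - th[ci])
    dt <- min(dt, 180 - dt)
    if (dt > thetaC || abs(gm[i] - gm[ci]) > gammaC) {
      labels[i] <- NA_integer_
    }
  }
  occ <- tabulate(labels, nbins = length(centers))
  keep <- which(occ > et * n)
  labels[!is.na(labels) & !(labels %in% keep)] <- NA_integer_
  labels <- match(labels, keep)
  out <- rep(NA_integer_, n)
  out[o] <- labels
  out
}

# compare two clusterings as partitions (identity up to label permutation,
# including agreement on unassigned points)
samePartition <- function(a, b) {
  if (length(a) != length(b)) {
    return(FALSE)
  }
  if (!identical(is.na(a), is.na(b))) {
    return(FALSE)
  }
  ok <- !is.na(a)
  a <- a[ok]
  b <- b[ok]
  if (length(a) == 0L) {
    return(TRUE)
  }
  pairs <- unique(paste(a, b))
  length(pairs) == length(unique(a)) &&
    length(pairs) == length(unique(b))
}
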