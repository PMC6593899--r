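#' Cluster elements ratio (CER)
#'
#' The occupancy of each cluster divided by the occupancy of the most
#' populated cluster: a vector of fractions in `(0, 1]` whose maximum is 1.
#'
#' @param occupancies positive occupancy vector, one entry per cluster.
#' @return CER vector, same length.
#' @examples
#' clusterElementsRatio(c(100, 50, 25))
#' @export
clusterElementsRatio <- function(occupancies) {
  if (length(occupancies) == 0L) {
    stop("'occupancies' must be nonempty", call. = FALSE)
  }
  if (any(occupancies <= 0)) {
    stop("'occupancies' must be positive", call. = FALSE)
  }
  occupancies / max(occupancies)
}

#' Cumulative CER distribution value
#'
#' Percentage of clusters whose CER is at or below a threshold — one point
#' of the cumulative CER distribution used to compare the cluster-population
#' uniformity of tissue regions.
#'
#' @param cer CER vector (from [clusterElementsRatio()]).
#' @param threshold fraction in `(0, 1]`.
#' @return percentage in `[0, 100]`.
#' @examples
#' cerCumulative(c(1, 0.5, 0.25), 0.6) # 66.67
#' @export
cerCumulative <- function(cer, threshold) {
  if (length(cer) == 0L) {
    stop("'cer' must be nonempty", call. = FALSE)
  }
  if (threshold <= 0 || threshold > 1) {
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  }
  100 * sum(cer <= threshold) / length(cer)
}

#' Fibril entropy of a cluster occupancy distribution
#'
#' Normalized Shannon entropy of the cluster occupancies,
#' \deqn{S = \frac{-\sum_i p_i \log p_i}{\log E_C}, \quad p_i = x_i / E_C,}
#' where `x_i` is the occupancy of cluster `i` and `E_C` the total number of
#' clustered elements. `S = 0` for a single cluster (perfect microstructural
#' order) and `S = 1` when every clustered element forms its own cluster
#' (maximal disorder). The log base cancels between numerator and
#' denominator; natural log is used internally. A single clustered element
#' (`E_C = 1`) returns 0 by convention.
#'
#' @param occupancies positive occupancy vector.
#' @return entropy in `[0, 1]`.
#' @examples
#' fibrilEntropy(5) # single cluster: 0
#' fibrilEntropy(c(1, 1, 1, 1)) # all singletons: 1
#' @export
setGeneric("fibrilEntropy", function(occupancies) {
  standardGeneric("fibrilEntropy")
})

#' @rdname fibrilEntropy
#' @export
setMethod("fibrilEntropy", "numeric", function(occupancies) {
  if (length(occupancies) == 0L) {
    stop("'occupancies' must be nonempty", call. = FALSE)
  }
  if (any(occupancies <= 0)) {
    stop("'occupancies' must be positive", call. = FALSE)
  }
  ec <- sum(occupancies)
  if (ec <= 1) {
    return(0)
  }
  p <- occupancies / ec
  h <- -sum(p * log(p))
  h / log(ec)
})

#' @rdname fibrilEntropy
#' @export
setMethod("fibrilEntropy", "ClusterModel", function(occupancies) {
  fibrilEntropy(occupancies@occupancies)
})

#' @rdname fibrilEntropy
#' @export
setMethod("fibrilEntropy", "PParams", function(occupancies) {
  occupancies@entropy
})

#' Phasor-space descriptors of a pruned cluster model
#'
#' Bundles the three descriptors of one region or ROI: number of retained
#' clusters, CER vector and fibril entropy, together with the total
#' clustered element count (pruned or unassigned pixels excluded).
#'
#' @param model a pruned [ClusterModel].
#' @return a [PParams].
#' @export
pParams <- function(model) {
  stopifnot(is(model, "ClusterModel"))
  k <- length(model@occupancies)
  if (k == 0L) {
    return(new("PParams", nClusters = 0L, cer = numeric(0),
               entropy = NA_real_, totalClustered = 0))
  }
  new("PParams",
    nClusters = k,
    cer = clusterElementsRatio(model@occupancies),
    entropy = fibrilEntropy(model@occupancies),
    totalClustered = sum(model@occupancies)
  )
}
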