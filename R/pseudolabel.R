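# Pseudo-labelling of the unlabelled pool: density-based clustering of CAE
# latent features. The neighbourhood radius Eps comes from the k-nearest-
# neighbour heuristic (mean distance of every point to its MinPts-th
# neighbour); MinPts defaults to min(2 * feature dimension, 10) when the
# caller does not fix it. Distances are plain Euclidean in double precision
# on the latent space, with no rescaling.

.featValues <- function(features) {
  if (is(features, "FeatureMatrix")) features@values else as.matrix(features)
}

#' Estimate the DBSCAN neighbourhood radius Eps
#'
#' Computes, for every point, the Euclidean distance to its
#' \code{minPts}-th nearest neighbour (self excluded) and returns the mean
#' of those distances -- the k-NN radius heuristic. The full sorted
#' k-distance curve is attached as \code{attr(, "kdist")} for elbow
#' diagnostics.
#'
#' @param features a [FeatureMatrix-class] or numeric matrix.
#' @param minPts neighbourhood size the radius should correspond to.
#' @return Positive scalar Eps with attribute \code{kdist}; a
#'   degenerate-geometry warning is raised when all k-distances are zero.
#' @examples
#' sq <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
#' estimateEps(sq, minPts = 1)  # every 1-NN distance is 1
#' @export
estimateEps <- function(features, minPts) {
  X <- .featValues(features)
  n <- nrow(X)
  minPts <- as.integer(minPts)
  if (n <= minPts)
    stop(sprintf("need more than minPts = %d points, got %d", minPts, n))
  D <- as.matrix(stats::dist(X))
  # D[i, -i] drops the self distance; with duplicated points the remaining
  # zeros are genuine zero-distance neighbours
  kdist <- vapply(seq_len(n), function(i) sort(D[i, -i])[minPts], numeric(1))
  eps <- mean(kdist)
  if (eps == 0)
    warning("all k-distances are zero (degenerate geometry); Eps = 0")
  structure(eps, kdist = sort(kdist))
}

#' Density-based clustering (DBSCAN)
#'
#' Core-point/density-reachability clustering from the textbook
#' definitions: a point is core when its closed Eps-neighbourhood (the
#' point itself included) holds at least \code{minPts} points; clusters are
#' the maximal density-connected sets; border points join the first cluster
#' that claims them in scan order; everything else is noise (-1).
#'
#' @param features a [FeatureMatrix-class] or numeric matrix.
#' @param eps neighbourhood radius (> 0).
#' @param minPts minimum closed-neighbourhood size of a core point.
#' @return A [ClusterResult-class]; noise is labelled -1.
#' @export
dbscanCluster <- function(features, eps, minPts) {
  X <- .featValues(features)
  if (!all(is.finite(X))) stop("features contain non-finite values")
  stopifnot(eps > 0, minPts >= 1)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nbrs) >= minPts
  labels <- rep(NA_integer_, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(nbrs[[i]], i)
    while (length(frontier)) {
      j <- frontier[1L]
      frontier <- frontier[-1L]
      if (is.na(labels[j])) {
        labels[j] <- cl
        if (core[j])
          frontier <- c(frontier, setdiff(nbrs[[j]],
                                          which(!is.na(labels))))
      }
    }
  }
  labels[is.na(labels)] <- -1L
  ClusterResult(labels)
}

#' Relabel an unlabelled pool by its clusters (the pretext set)
#'
#' Turns a clustering of the pool into a pseudo-labelled training set for
#' the self-supervised pretext task: cluster ids become class labels named
#' \code{pseudo_0 ..}. Noise samples are dropped by default, or kept as an
#' explicit \code{pseudo_noise} class.
#'
#' @param pool the unlabelled [LabeledImageSet-class], in clustering order.
#' @param clusters a [ClusterResult-class] aligned with \code{pool}.
#' @param dropNoise drop noise samples (default) instead of keeping them as
#'   a class.
#' @return A [LabeledImageSet-class] with pseudo-class labels.
#' @export
makePretextSet <- function(pool, clusters, dropNoise = TRUE) {
  lab <- clusterLabels(clusters)
  if (length(lab) != nImages(pool))
    stop("cluster labels are not aligned with the pool")
  if (all(lab == -1L))
    stop("every sample is noise; revise eps/minPts before pretext training")
  k <- nClusters(clusters)
  if (dropNoise) {
    keep <- which(lab != -1L)
    sub <- pool[keep]
    new("LabeledImageSet", images = images(sub), labels = lab[keep],
        subLabels = NULL,
        classNames = sprintf("pseudo_%d", seq_len(k) - 1L),
        split = splitTags(sub), metadata = pool@metadata)
  } else {
    relab <- ifelse(lab == -1L, k, lab)
    new("LabeledImageSet", images = images(pool), labels = as.integer(relab),
        subLabels = NULL,
        classNames = c(sprintf("pseudo_%d", seq_len(k) - 1L),
                       "pseudo_noise"),
        split = splitTags(pool), metadata = pool@metadata)
  }
}

#' Default MinPts heuristic
#'
#' Twice the feature dimensionality, capped at 10 -- the usual rule of
#' thumb when no value is dictated by the data.
#'
#' @param features a [FeatureMatrix-class] or matrix.
#' @return Integer MinPts.
#' @export
defaultMinPts <- function(features) {
  min(2L * ncol(.featValues(features)), 10L)
}
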