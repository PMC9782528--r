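# Class decomposition: per original class, extract backbone features,
# reduce them by PCA, cluster by affinity propagation over cosine
# similarities (or by the fixed-k k-means baseline of the DeTraC lineage),
# and relabel the dataset with the resulting sub-classes. The affinity
# propagation message passing is authored here from the responsibility /
# availability update equations; PCA and k-means are delegated to stats.

#' Backbone features per original class
#'
#' Runs the backbone forward over each class of the dataset and stacks
#' per-image feature rows, giving the per-class matrices the decomposition
#' clusters. Two feature readouts are available: the raw activations of one
#' named layer (e.g. the penultimate fully connected activation,
#' \code{"relu_fc1"}), or orderless texture statistics -- the spatial mean
#' and standard deviation of every feature map of the named convolutional
#' activation layer(s) (\code{spatialStats = TRUE}, the default used by
#' [decomposeDataset()]). The pooled statistics are insensitive to where a
#' texture happens to sit in the patch, which keeps a within-class
#' appearance mode a single compact cluster.
#'
#' @param dataset a [LabeledImageSet-class].
#' @param backbone a trained classifier from [trainClassifier()].
#' @param layer layer name, or a vector of convolutional activation names
#'   when \code{spatialStats} is set; see [availableLayers()].
#' @param spatialStats summarise each feature map by its spatial mean and
#'   standard deviation instead of returning raw activations.
#' @return Named list (one entry per class name) of
#'   [FeatureMatrix-class] objects, rows in within-class dataset order.
#' @export
backboneClassFeatures <- function(dataset, backbone, layer = "relu_fc1",
                                  spatialStats = FALSE) {
  stopifnot(inherits(backbone, "CNNClassifier"))
  X <- .flattenImages(images(dataset)) - .IMG_CENTER
  fwd <- .nnForward(backbone$net, X)
  feats <- NULL
  for (ly in layer) {
    li <- .layerIndex(backbone$net, ly)
    acts <- fwd$acts[[li + 1L]]
    if (spatialStats) {
      shape <- backbone$net$shapes[[li + 1L]]
      if (length(shape) != 3L)
        stop(sprintf("layer '%s' has no spatial dimensions", ly))
      A <- array(t(acts), c(shape[1L] * shape[2L], shape[3L], nrow(acts)))
      feats <- cbind(feats, t(apply(A, c(2L, 3L), mean)),
                     t(apply(A, c(2L, 3L), stats::sd)))
    } else {
      if (length(layer) > 1L)
        stop("multiple layers require spatialStats = TRUE")
      feats <- acts
    }
  }
  out <- list()
  for (k in seq_along(classNames(dataset))) {
    idx <- which(imageLabels(dataset) == k - 1L)
    out[[classNames(dataset)[k]]] <-
      FeatureMatrix(feats[idx, , drop = FALSE],
                    sampleIds = sprintf("s%d", idx), source = "backbone")
  }
  out
}

.convActivations <- function(net) {
  convIdx <- which(vapply(net$layers, function(l) l$type == "conv",
                          logical(1)))
  vapply(convIdx, function(i) {
    if (i < length(net$layers) && net$layers[[i + 1L]]$type == "relu")
      net$layers[[i + 1L]]$name
    else net$layers[[i]]$name
  }, "")
}

#' PCA reduction to an explained-variance target
#'
#' Centres the features and keeps the smallest number of leading principal
#' components whose cumulative explained-variance ratio reaches
#' \code{varianceThreshold}.
#'
#' @param features a [FeatureMatrix-class] or numeric matrix (>= 2 rows).
#' @param varianceThreshold real in (0, 1]; default 0.95.
#' @return A list with \code{features} (the projected
#'   [FeatureMatrix-class]), \code{nComponents}, \code{explained} (all
#'   explained-variance ratios, non-increasing) and \code{rotation}.
#' @examples
#' x <- matrix(rnorm(40), 20, 2) %*% diag(c(3, 1))
#' pcaReduce(x, 0.9)$nComponents
#' @export
pcaReduce <- function(features, varianceThreshold = 0.95) {
  X <- .featValues(features)
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples")
  stopifnot(varianceThreshold > 0, varianceThreshold <= 1)
  vars <- apply(X, 2L, stats::var)
  if (all(vars < 1e-24)) {
    warning("zero-variance features; returning a single constant component")
    fm <- FeatureMatrix(matrix(0, nrow(X), 1L),
                        sampleIds = if (is(features, "FeatureMatrix"))
                          features@sampleIds else NULL,
                        source = if (is(features, "FeatureMatrix"))
                          features@source else "backbone")
    return(list(features = fm, nComponents = 1L, explained = 1,
                rotation = matrix(0, ncol(X), 1L)))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  m <- which(cumsum(ratio) >= varianceThreshold - 1e-12)[1L]
  fm <- FeatureMatrix(pc$x[, seq_len(m), drop = FALSE],
                      sampleIds = if (is(features, "FeatureMatrix"))
                        features@sampleIds else NULL,
                      source = if (is(features, "FeatureMatrix"))
                        features@source else "backbone")
  list(features = fm, nComponents = m, explained = ratio,
       rotation = pc$rotation[, seq_len(m), drop = FALSE])
}

#' Cosine similarity matrix
#'
#' \eqn{s(i,j) = \langle x_i, x_j\rangle / (\|x_i\| \|x_j\|)}: 1 for equal
#' orientation, 0 for orthogonal vectors. The diagonal is later overwritten
#' by the affinity-propagation preference.
#'
#' @param features a [FeatureMatrix-class] or numeric matrix without
#'   all-zero rows.
#' @return n x n numeric matrix with attribute \code{kind = "cosine"}.
#' @export
cosineSimilarity <- function(features) {
  X <- .featValues(features)
  nrm <- sqrt(rowSums(X^2))
  bad <- which(nrm == 0)
  if (length(bad))
    stop(sprintf("zero-norm feature row(s): %s",
                 paste(bad, collapse = ", ")))
  S <- tcrossprod(X / nrm)
  S <- pmin(pmax(S, -1), 1)
  attr(S, "kind") <- "cosine"
  S
}

#' Negative squared Euclidean similarity matrix
#'
#' The classical affinity-propagation similarity
#' \eqn{s(i,j) = -\|x_i - x_j\|^2}.
#'
#' @param features a [FeatureMatrix-class] or numeric matrix.
#' @return n x n numeric matrix with attribute
#'   \code{kind = "neg_sq_euclidean"}.
#' @export
negSqEuclidean <- function(features) {
  X <- .featValues(features)
  S <- -as.matrix(stats::dist(X))^2
  attr(S, "kind") <- "neg_sq_euclidean"
  S
}

#' Affinity propagation clustering
#'
#' Exemplar-based clustering by damped message passing. Each iteration
#' updates the responsibility matrix
#' \eqn{\rho(i,k) = s(i,k) - \max_{k' \ne k}\{a(i,k') + s(i,k')\}} and the
#' availability matrix
#' \eqn{a(i,k) = \min\{0, \rho(k,k) + \sum_{i' \notin \{i,k\}}
#' \max(0, \rho(i',k))\}} (with
#' \eqn{a(k,k) = \sum_{i' \ne k} \max(0, \rho(i',k))}), mixing new into old
#' messages as \eqn{\lambda \cdot old + (1-\lambda) \cdot new}. Points
#' \eqn{k} with \eqn{\rho(k,k) + a(k,k) > 0} are the exemplars; every other
#' point joins the exemplar with the largest similarity (lowest index on
#' ties). Iteration stops when the exemplar set is unchanged for
#' \code{convIter} consecutive iterations, or at \code{maxIter} with
#' \code{converged = FALSE}.
#'
#' @param S similarity matrix (e.g. [cosineSimilarity()]).
#' @param preference diagonal self-similarity controlling the emergent
#'   cluster count: a number (or per-point vector), or one of
#'   \code{"low"} (the default: one off-diagonal spread below the minimum
#'   similarity, \code{2*min - max}, which only creates an exemplar when
#'   genuine cluster structure supports it), \code{"median"} or
#'   \code{"min"} (the classical moderate and small cluster-count
#'   choices).
#' @param damping message damping \eqn{\lambda} in [0.5, 1); default 0.9.
#' @param maxIter iteration cap (default 1000).
#' @param convIter consecutive stable iterations required (default 50).
#' @return A [ClusterResult-class] with exemplars; no noise labels. The
#'   attributes \code{converged} and \code{iterations} report termination.
#' @export
affinityPropagation <- function(S, preference = "low", damping = 0.9,
                                maxIter = 1000L, convIter = 50L) {
  S <- unname(as.matrix(S))
  n <- nrow(S)
  if (n < 1L) stop("similarity matrix is empty")
  stopifnot(damping >= 0.5, damping < 1)
  if (n == 1L)
    return(ClusterResult(0L, exemplars = 1L, converged = TRUE,
                         iterations = 0L))
  off <- S[row(S) != col(S)]
  if (max(off) - min(off) < 1e-15) {
    warning("all similarities equal; returning a single cluster")
    return(ClusterResult(rep(0L, n), exemplars = 1L))
  }
  if (is.character(preference))
    preference <- switch(match.arg(preference, c("low", "median", "min")),
                         low = 2 * min(off) - max(off),
                         median = stats::median(off),
                         min = min(off))
  diag(S) <- preference
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  prevEx <- integer(0)
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    # responsibilities: subtract, per row, the best competing a + s
    AS <- A + S
    i1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), i1)]
    AS2 <- AS
    AS2[cbind(seq_len(n), i1)] <- -Inf
    m2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), i1)] <- S[cbind(seq_len(n), i1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    colPos <- colSums(Rp)              # sum over all i' of max(0, R(i',k))
    selfTerm <- diag(R) + (colPos - diag(Rp))
    Anew <- pmin(matrix(selfTerm, n, n, byrow = TRUE) - Rp, 0)
    diag(Anew) <- colPos - diag(Rp)
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, prevEx) && length(ex)) {
      stable <- stable + 1L
      if (stable >= convIter) { converged <- TRUE; break }
    } else stable <- 0L
    prevEx <- ex
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (!length(ex)) ex <- which.max(diag(R) + diag(A))
  assign <- apply(S[, ex, drop = FALSE], 1L, which.max)  # lowest index wins
  assign[ex] <- seq_along(ex)
  ClusterResult(assign - 1L, exemplars = ex, converged = converged,
                iterations = it)
}

#' k-means decomposition baseline
#'
#' Fixed-k clustering used by the DeTraC/4S-DT lineage (k = 2 per class).
#' Lloyd iterations with \code{nstart} seeded random restarts, keeping the
#' lowest within-cluster sum of squares.
#'
#' @param features a [FeatureMatrix-class] or numeric matrix.
#' @param k number of clusters (n >= k).
#' @param seed integer seed.
#' @param nstart random restarts (default 10).
#' @return A [ClusterResult-class]; no noise labels.
#' @export
kmeansDecompose <- function(features, k = 2L, seed = 1L, nstart = 10L) {
  X <- .featValues(features)
  if (nrow(X) < k) stop("need at least k samples")
  set.seed(seed)
  if (k == 1L) return(ClusterResult(rep(0L, nrow(X))))
  km <- suppressWarnings(
    stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L,
                  algorithm = "Lloyd"))
  ClusterResult(km$cluster - 1L)
}

#' Decompose a labelled dataset into sub-classes
#'
#' Applies per-class cluster assignments to relabel dataset A (original
#' labels L) as dataset B (sub-class labels C): each class's clusters
#' become sub-classes named \code{<class>_<j>}. The sample count is
#' conserved exactly, and composing the parent map over the assignment
#' recovers the original label of every sample.
#'
#' @param dataset a [LabeledImageSet-class] (dataset A).
#' @param perClassClusters named list mapping every class name to a
#'   [ClusterResult-class] over that class's samples (in within-class
#'   dataset order); noise labels are not admitted.
#' @param method tag recorded in the map: \code{"ap"}, \code{"kmeans"} or
#'   \code{"identity"}.
#' @return A list with \code{dataset} (dataset B, whose labels are
#'   sub-class codes and whose \code{subLabels} mirror them) and \code{map}
#'   (a [DecompositionMap-class]).
#' @export
decomposeClasses <- function(dataset, perClassClusters, method = "ap") {
  cn <- classNames(dataset)
  missing <- setdiff(cn, names(perClassClusters))
  if (length(missing))
    stop(sprintf("no cluster result for class(es): %s",
                 paste(missing, collapse = ", ")))
  subNames <- character(0)
  parentOf <- character(0)
  childrenOf <- list()
  assignment <- character(nImages(dataset))
  for (k in seq_along(cn)) {
    cl <- perClassClusters[[cn[k]]]
    idx <- which(imageLabels(dataset) == k - 1L)
    lab <- clusterLabels(cl)
    if (length(lab) != length(idx))
      stop(sprintf("cluster result for class '%s' covers %d samples, expected %d",
                   cn[k], length(lab), length(idx)))
    if (any(lab == -1L))
      stop(sprintf("noise labels are not allowed in decomposition (class '%s')",
                   cn[k]))
    ch <- sprintf("%s_%d", cn[k], seq_len(nClusters(cl)) - 1L)
    childrenOf[[cn[k]]] <- ch
    parentOf[ch] <- cn[k]
    subNames <- c(subNames, ch)
    assignment[idx] <- ch[lab + 1L]
  }
  map <- new("DecompositionMap", parentOf = parentOf,
             childrenOf = childrenOf, assignment = assignment,
             method = method)
  codes <- match(assignment, subNames) - 1L
  setB <- new("LabeledImageSet", images = images(dataset),
              labels = codes, subLabels = codes, classNames = subNames,
              split = splitTags(dataset), metadata = dataset@metadata)
  list(dataset = setB, map = map)
}

#' Identity decomposition (one sub-class per class)
#'
#' The degenerate map used by the no-decomposition baseline: every class is
#' its own single sub-class.
#'
#' @param dataset a [LabeledImageSet-class].
#' @return As [decomposeClasses()], with method \code{"identity"}.
#' @export
identityDecomposition <- function(dataset) {
  cls <- lapply(classNames(dataset), function(cn)
    ClusterResult(rep(0L, sum(imageLabels(dataset) ==
                                match(cn, classNames(dataset)) - 1L))))
  names(cls) <- classNames(dataset)
  decomposeClasses(dataset, cls, method = "identity")
}

#' Full per-class decomposition pipeline
#'
#' Convenience wrapper chaining [backboneClassFeatures()], [pcaReduce()],
#' [cosineSimilarity()] and [affinityPropagation()] (or
#' [kmeansDecompose()]) per class, then [decomposeClasses()].
#'
#' @param dataset a [LabeledImageSet-class].
#' @param backbone trained classifier supplying features.
#' @param method \code{"ap"} or \code{"kmeans"}.
#' @param pcaThreshold explained-variance target for [pcaReduce()].
#' @param damping,maxIter,convIter affinity-propagation settings.
#' @param k k-means cluster count per class.
#' @param layer backbone layer(s) to take features from; \code{NULL}
#'   (default) uses spatial mean/sd statistics of every convolutional
#'   activation.
#' @param seed integer seed (k-means restarts).
#' @param ensureTrainCoverage when the dataset carries splits, merge any
#'   sub-cluster that has no training-split member into the sibling
#'   sub-cluster with the most training members (classifier training
#'   requires every label in the training split).
#' @return As [decomposeClasses()], plus \code{perClass} diagnostics
#'   (cluster results and PCA component counts).
#' @export
decomposeDataset <- function(dataset, backbone, method = c("ap", "kmeans"),
                             pcaThreshold = 0.95, damping = 0.9,
                             maxIter = 1000L, convIter = 50L, k = 2L,
                             layer = NULL, seed = 1L,
                             ensureTrainCoverage = TRUE) {
  method <- match.arg(method)
  spatialStats <- is.null(layer)
  if (spatialStats) layer <- .convActivations(backbone$net)
  feats <- backboneClassFeatures(dataset, backbone, layer = layer,
                                 spatialStats = spatialStats)
  perClass <- list()
  nComp <- integer(0)
  for (cn in names(feats)) {
    red <- pcaReduce(feats[[cn]], pcaThreshold)
    nComp[cn] <- red$nComponents
    perClass[[cn]] <- if (method == "ap") {
      affinityPropagation(cosineSimilarity(red$features),
                          damping = damping, maxIter = maxIter,
                          convIter = convIter)
    } else {
      kmeansDecompose(red$features, k = k, seed = seed)
    }
  }
  if (ensureTrainCoverage && length(splitTags(dataset)))
    perClass <- .mergeUncoveredClusters(dataset, perClass)
  out <- decomposeClasses(dataset, perClass, method = method)
  out$perClass <- perClass
  out$nComponents <- nComp
  out
}

# merge clusters with no train-split member into the sibling with the most
# training members, then compact cluster ids
.mergeUncoveredClusters <- function(dataset, perClass) {
  for (cn in names(perClass)) {
    k <- match(cn, classNames(dataset)) - 1L
    idx <- which(imageLabels(dataset) == k)
    lab <- clusterLabels(perClass[[cn]])
    inTrain <- splitTags(dataset)[idx] == "train"
    trainCounts <- vapply(seq_len(nClusters(perClass[[cn]])) - 1L,
                          function(c) sum(lab == c & inTrain), integer(1))
    if (all(trainCounts > 0L)) next
    target <- which.max(trainCounts) - 1L
    lab[lab %in% (which(trainCounts == 0L) - 1L)] <- target
    lab <- match(lab, sort(unique(lab))) - 1L
    perClass[[cn]] <- ClusterResult(lab)
  }
  perClass
}
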