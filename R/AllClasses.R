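#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Labelled image set
#'
#' Container for a stack of equally sized images with integer class labels,
#' optional ground-truth sub-cluster labels, class names and train/val/test
#' split tags. Images are stored as a 4-dimensional array
#' (height x width x channels x n) with intensities in [0, 1]. Labels are
#' 0-based codes into \code{classNames} (so \code{classNames[label + 1]} is
#' the class of an image), which keeps the label space explicit when classes
#' are decomposed and recomposed.
#'
#' @slot images numeric array, height x width x channels x n, values in [0,1].
#' @slot labels integer vector of 0-based class codes, one per image.
#' @slot subLabels integer vector of 0-based sub-cluster codes (ground truth
#'   or assigned), or \code{NULL} when absent.
#' @slot classNames character vector naming the classes, in label-code order.
#' @slot split character vector of per-image tags in
#'   \code{c("train","val","test")}, or empty when no split is assigned.
#' @slot metadata list of free-form annotations (e.g. planted-patch boxes,
#'   generating motif parameters).
#'
#' @seealso [generateLabeled()], [readImageSet()], [assignSplits()]
#' @export
setClass("LabeledImageSet",
  representation(
    images = "array",
    labels = "integer",
    subLabels = "integerOrNULL",
    classNames = "character",
    split = "character",
    metadata = "list"
  ),
  prototype(
    images = array(0, c(1, 1, 1, 0)),
    labels = integer(0),
    subLabels = NULL,
    classNames = character(0),
    split = character(0),
    metadata = list()
  )
)

setValidity("LabeledImageSet", function(object) {
  msg <- character(0)
  d <- dim(object@images)
  if (length(d) != 4L)
    msg <- c(msg, "images must be a 4-d array (h x w x channels x n)")
  else {
    n <- d[4L]
    if (length(object@labels) != n)
      msg <- c(msg, "length(labels) must equal the number of images")
    if (!(d[3L] %in% c(1L, 3L)))
      msg <- c(msg, "images must have 1 or 3 channels")
    if (n > 0 && (anyNA(object@labels) ||
                  min(object@labels) < 0L ||
                  max(object@labels) >= length(object@classNames)))
      msg <- c(msg, "labels must lie in [0, length(classNames))")
    if (!is.null(object@subLabels)) {
      if (length(object@subLabels) != n)
        msg <- c(msg, "subLabels must have one entry per image")
      else if (n > 0) {
        ok <- !is.na(object@subLabels)
        if (any(ok)) {
          tab <- unique(cbind(object@subLabels[ok], object@labels[ok]))
          if (anyDuplicated(tab[, 1L]))
            msg <- c(msg, "each sub-label must map to exactly one label")
        }
      }
    }
    if (length(object@split) > 0) {
      if (length(object@split) != n)
        msg <- c(msg, "split must have one tag per image")
      if (!all(object@split %in% c("train", "val", "test")))
        msg <- c(msg, "split tags must be 'train', 'val' or 'test'")
    }
  }
  if (anyDuplicated(object@classNames))
    msg <- c(msg, "classNames must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledImageSet
#'
#' @param images array h x w x c x n (a h x w x n array is promoted to one
#'   channel), intensities in [0, 1].
#' @param labels integer 0-based class codes per image.
#' @param classNames character class names; defaults to
#'   \code{class_0 .. class_{K-1}}.
#' @param subLabels optional integer 0-based sub-cluster codes.
#' @param split optional character split tags.
#' @param metadata optional list of annotations.
#' @return A [LabeledImageSet-class] object.
#' @export
LabeledImageSet <- function(images, labels, classNames = NULL,
                            subLabels = NULL, split = character(0),
                            metadata = list()) {
  if (length(dim(images)) == 3L)
    dim(images) <- c(dim(images)[1:2], 1L, dim(images)[3L])
  labels <- as.integer(labels)
  if (is.null(classNames)) {
    k <- if (length(labels)) max(labels) + 1L else 0L
    classNames <- sprintf("class_%d", seq_len(k) - 1L)
  }
  new("LabeledImageSet", images = images, labels = labels,
      subLabels = if (is.null(subLabels)) NULL else as.integer(subLabels),
      classNames = as.character(classNames), split = as.character(split),
      metadata = metadata)
}

#' Feature matrix
#'
#' An n x d real-valued embedding of images: rows are samples (in dataset
#' order), columns are latent or backbone features.
#'
#' @slot values numeric matrix, n x d, all entries finite.
#' @slot sampleIds character vector of row identifiers.
#' @slot source character, \code{"cae_latent"} or \code{"backbone"}.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", sampleIds = "character",
                 source = "character"))

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be numeric")
  else if (length(object@values) && !all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (nrow(object@values) != length(object@sampleIds))
    msg <- c(msg, "one sampleId per row required")
  if (!(object@source %in% c("cae_latent", "backbone", "pixels")))
    msg <- c(msg, "source must be 'cae_latent', 'backbone' or 'pixels'")
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureMatrix-class
#' @param values numeric matrix n x d.
#' @param sampleIds optional character row identifiers.
#' @param source provenance tag.
#' @export
FeatureMatrix <- function(values, sampleIds = NULL, source = "backbone") {
  values <- as.matrix(values)
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(values))) rownames(values)
                 else sprintf("s%d", seq_len(nrow(values)))
  new("FeatureMatrix", values = values, sampleIds = as.character(sampleIds),
      source = source)
}

#' Clustering result
#'
#' Per-sample cluster assignment with the conventional reserved noise label
#' -1 (density clustering only; affinity propagation and k-means label every
#' point). Affinity propagation additionally records its exemplars as sample
#' indices.
#'
#' @slot labels integer per sample: -1 for noise, otherwise 0-based ids.
#' @slot nClusters integer count of non-noise clusters.
#' @slot exemplars integer 1-based sample indices of cluster exemplars
#'   (affinity propagation), or \code{NULL}.
#' @slot converged logical; message-passing termination state (NA for
#'   methods without an iterative convergence notion).
#' @slot iterations integer; iterations run (NA when not applicable).
#' @export
setClass("ClusterResult",
  representation(labels = "integer", nClusters = "integer",
                 exemplars = "integerOrNULL", converged = "logical",
                 iterations = "integer"),
  prototype(exemplars = NULL, converged = NA, iterations = NA_integer_))

setValidity("ClusterResult", function(object) {
  msg <- character(0)
  lab <- object@labels
  k <- object@nClusters
  if (length(lab) && (min(lab) < -1L || max(lab) >= k))
    msg <- c(msg, "labels must lie in {-1, 0, .., nClusters-1}")
  if (k > 0 && !all((seq_len(k) - 1L) %in% lab))
    msg <- c(msg, "every non-noise cluster must have at least one member")
  if (!is.null(object@exemplars) && length(object@exemplars) != k)
    msg <- c(msg, "one exemplar per cluster required")
  if (length(msg)) msg else TRUE
})

ClusterResult <- function(labels, exemplars = NULL, converged = NA,
                          iterations = NA_integer_) {
  labels <- as.integer(labels)
  k <- if (length(labels) && any(labels >= 0L)) max(labels) + 1L else 0L
  new("ClusterResult", labels = labels, nClusters = as.integer(k),
      exemplars = if (is.null(exemplars)) NULL else as.integer(exemplars),
      converged = converged, iterations = as.integer(iterations))
}

#' Class-decomposition map
#'
#' Records the bijective bookkeeping between original class labels and the
#' generated sub-class labels: which parent each sub-label belongs to, the
#' ordered sub-labels of each parent, and the per-sample sub-label
#' assignment. Sample count is conserved: decomposition relabels, it never
#' drops or duplicates images.
#'
#' @slot parentOf named character: sub-label name -> parent class name.
#' @slot childrenOf named list: parent class name -> character vector of its
#'   sub-label names, in sub-cluster order.
#' @slot assignment character per-sample sub-label names, in dataset order.
#' @slot method character, \code{"ap"}, \code{"kmeans"} or
#'   \code{"identity"}.
#' @export
setClass("DecompositionMap",
  representation(parentOf = "character", childrenOf = "list",
                 assignment = "character", method = "character"))

setValidity("DecompositionMap", function(object) {
  msg <- character(0)
  for (p in names(object@childrenOf)) {
    ch <- object@childrenOf[[p]]
    if (!all(ch %in% names(object@parentOf)) ||
        !all(object@parentOf[ch] == p))
      msg <- c(msg, sprintf("childrenOf['%s'] inconsistent with parentOf", p))
  }
  if (!setequal(names(object@parentOf), unlist(object@childrenOf)))
    msg <- c(msg, "parentOf and childrenOf must cover the same sub-labels")
  if (length(object@assignment) &&
      !all(object@assignment %in% names(object@parentOf)))
    msg <- c(msg, "assignment uses sub-labels absent from the map")
  if (length(object@assignment) &&
      !all(names(object@parentOf) %in% object@assignment))
    msg <- c(msg, "every sub-label must have at least one assigned sample")
  if (!(object@method %in% c("ap", "kmeans", "identity")))
    msg <- c(msg, "method must be 'ap', 'kmeans' or 'identity'")
  if (length(msg)) msg else TRUE
})

#' Row-stochastic class-probability table
#'
#' @slot probs numeric matrix n x K, rows summing to one; column names are
#'   the label names.
#' @slot truth integer 0-based true-label codes per row.
#' @export
setClass("ProbabilityTable",
  representation(probs = "matrix", truth = "integer"))

setValidity("ProbabilityTable", function(object) {
  msg <- character(0)
  p <- object@probs
  if (is.null(colnames(p)))
    msg <- c(msg, "probs must have label names as colnames")
  if (length(p)) {
    if (min(p) < -1e-9) msg <- c(msg, "probabilities must be non-negative")
    if (max(abs(rowSums(p) - 1)) > 1e-6)
      msg <- c(msg, "rows must sum to 1 within 1e-6")
  }
  if (length(object@truth) != nrow(p))
    msg <- c(msg, "one truth code per row required")
  if (length(object@truth) &&
      (min(object@truth) < 0L || max(object@truth) >= ncol(p)))
    msg <- c(msg, "truth codes must index probs columns")
  if (length(msg)) msg else TRUE
})

ProbabilityTable <- function(probs, truth) {
  new("ProbabilityTable", probs = as.matrix(probs), truth = as.integer(truth))
}

#' Classification metrics report
#'
#' Accuracy, macro-averaged one-vs-rest sensitivity and specificity (all in
#' percent), per-class ROC AUC and the confusion matrix (rows = truth,
#' columns = prediction).
#'
#' @slot accuracy numeric percentage.
#' @slot sensitivity numeric macro-averaged percentage.
#' @slot specificity numeric macro-averaged percentage.
#' @slot perClassAUC named numeric in [0, 1].
#' @slot confusion integer matrix, rows truth, columns prediction.
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", perClassAUC = "numeric",
                 confusion = "matrix"))

#' Grad-CAM explanation result
#'
#' @slot weights numeric gradient-pooled weight per feature map.
#' @slot rawMap numeric matrix at feature-map resolution, entries >= 0.
#' @slot heatmap numeric matrix at input resolution, min-max normalised to
#'   [0, 1] (all zeros when the rectified map is identically zero).
#' @slot targetClass integer 0-based class code the map explains.
#' @slot layer character name of the convolutional activation used.
#' @slot children list of per-child GradCAMResult objects when the map was
#'   composed over a parent class's sub-classes.
#' @export
setClass("GradCAMResult",
  representation(weights = "numeric", rawMap = "matrix", heatmap = "matrix",
                 targetClass = "integer", layer = "character",
                 children = "list"),
  prototype(children = list()))

setValidity("GradCAMResult", function(object) {
  msg <- character(0)
  if (length(object@rawMap) && min(object@rawMap) < -1e-12)
    msg <- c(msg, "rawMap must be non-negative")
  if (length(object@heatmap) &&
      (min(object@heatmap) < -1e-12 || max(object@heatmap) > 1 + 1e-9))
    msg <- c(msg, "heatmap must be normalised to [0, 1]")
  if (length(msg)) msg else TRUE
})
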