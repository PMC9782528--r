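#' Accessors for ClassDecomp data objects
#'
#' Standard slot accessors. \code{images()} returns the h x w x c x n image
#' array, \code{imageLabels()} the 0-based class codes, \code{subLabels()}
#' the 0-based sub-cluster codes (or \code{NULL}), \code{classNames()} the
#' label names, \code{splitTags()} the per-image split assignment and
#' \code{nImages()} the stack size. For clustering results,
#' \code{clusterLabels()}, \code{nClusters()} and \code{exemplars()} expose
#' the assignment; for decomposition maps, \code{parentOf()},
#' \code{childrenOf()} and \code{subAssignment()} expose the label algebra.
#'
#' @param x a ClassDecomp object.
#' @return The slot value, documented per accessor above.
#' @name accessors
#' @aliases images imageLabels subLabels classNames splitTags nImages
#'   clusterLabels nClusters exemplars parentOf childrenOf subAssignment
NULL

#' @rdname accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))
#' @rdname accessors
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))
#' @rdname accessors
#' @export
setGeneric("subLabels", function(x) standardGeneric("subLabels"))
#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setGeneric("splitTags", function(x) standardGeneric("splitTags"))
#' @rdname accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("exemplars", function(x) standardGeneric("exemplars"))
#' @rdname accessors
#' @export
setGeneric("hasConverged", function(x) standardGeneric("hasConverged"))
#' @rdname accessors
#' @export
setGeneric("parentOf", function(x) standardGeneric("parentOf"))
#' @rdname accessors
#' @export
setGeneric("childrenOf", function(x) standardGeneric("childrenOf"))
#' @rdname accessors
#' @export
setGeneric("subAssignment", function(x) standardGeneric("subAssignment"))

#' @rdname accessors
setMethod("images", "LabeledImageSet", function(x) x@images)
#' @rdname accessors
setMethod("imageLabels", "LabeledImageSet", function(x) x@labels)
#' @rdname accessors
setMethod("subLabels", "LabeledImageSet", function(x) x@subLabels)
#' @rdname accessors
setMethod("classNames", "LabeledImageSet", function(x) x@classNames)
#' @rdname accessors
setMethod("splitTags", "LabeledImageSet", function(x) x@split)
#' @rdname accessors
setMethod("nImages", "LabeledImageSet", function(x) dim(x@images)[4L])

#' @rdname accessors
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)
#' @rdname accessors
setMethod("nClusters", "ClusterResult", function(x) x@nClusters)
#' @rdname accessors
setMethod("exemplars", "ClusterResult", function(x) x@exemplars)
#' @rdname accessors
setMethod("hasConverged", "ClusterResult", function(x) x@converged)

#' @rdname accessors
setMethod("parentOf", "DecompositionMap", function(x) x@parentOf)
#' @rdname accessors
setMethod("childrenOf", "DecompositionMap", function(x) x@childrenOf)
#' @rdname accessors
setMethod("subAssignment", "DecompositionMap", function(x) x@assignment)

#' @describeIn LabeledImageSet-class subset the image stack by image index.
#' @param x,i object and image indices.
#' @param j,drop,... ignored (images are always kept 4-d).
#' @export
setMethod("[", "LabeledImageSet", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nImages(x))[i]
  new("LabeledImageSet",
      images = x@images[, , , idx, drop = FALSE],
      labels = x@labels[idx],
      subLabels = if (is.null(x@subLabels)) NULL else x@subLabels[idx],
      classNames = x@classNames,
      split = if (length(x@split)) x@split[idx] else character(0),
      metadata = x@metadata)
})

#' @describeIn FeatureMatrix-class coerce to a base matrix with sampleIds as
#'   rownames.
#' @param x a FeatureMatrix.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "FeatureMatrix", function(x, ...) {
  m <- x@values
  rownames(m) <- x@sampleIds
  m
})

#' @rdname accessors
setMethod("nImages", "FeatureMatrix", function(x) nrow(x@values))

setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

setMethod("show", "LabeledImageSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("LabeledImageSet: %d image(s), %dx%d, %d channel(s)\n",
              d[4L], d[1L], d[2L], d[3L]))
  if (length(object@classNames)) {
    tab <- table(factor(object@classNames[object@labels + 1L],
                        levels = object@classNames))
    cat("  classes:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  if (length(object@split))
    cat("  split:", paste(sprintf("%s=%d", names(table(object@split)),
                                  table(object@split)), collapse = " "), "\n")
  if (!is.null(object@subLabels))
    cat("  sub-labels:", length(unique(stats::na.omit(object@subLabels))),
        "distinct\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d x %d [%s]\n", nrow(object@values),
              ncol(object@values), object@source))
})

setMethod("show", "ClusterResult", function(object) {
  noise <- sum(object@labels == -1L)
  cat(sprintf("ClusterResult: %d cluster(s), %d sample(s), %d noise\n",
              object@nClusters, length(object@labels), noise))
  if (!is.null(object@exemplars))
    cat("  exemplars:", paste(object@exemplars, collapse = ", "), "\n")
})

setMethod("show", "DecompositionMap", function(object) {
  cat(sprintf("DecompositionMap [%s]: %d class(es) -> %d sub-class(es)\n",
              object@method, length(object@childrenOf),
              length(object@parentOf)))
  for (p in names(object@childrenOf)) {
    ch <- object@childrenOf[[p]]
    sz <- vapply(ch, function(s) sum(object@assignment == s), integer(1))
    cat(sprintf("  %s: %s\n", p,
                paste(sprintf("%s (%d)", ch, sz), collapse = ", ")))
  }
})

setMethod("show", "ProbabilityTable", function(object) {
  cat(sprintf("ProbabilityTable: %d sample(s) x %d label(s)\n",
              nrow(object@probs), ncol(object@probs)))
  cat("  labels:", paste(colnames(object@probs), collapse = ", "), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: ACC %.2f%%  SN %.2f%%  SP %.2f%%\n",
              object@accuracy, object@sensitivity, object@specificity))
  cat("  AUC:", paste(sprintf("%s=%.3f", names(object@perClassAUC),
                              object@perClassAUC), collapse = " "), "\n")
})

setMethod("show", "GradCAMResult", function(object) {
  cat(sprintf(
    "GradCAMResult: class %d, layer '%s', map %dx%d -> heatmap %dx%d\n",
    object@targetClass, object@layer, nrow(object@rawMap),
    ncol(object@rawMap), nrow(object@heatmap), ncol(object@heatmap)))
})
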