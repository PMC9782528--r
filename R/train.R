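# Classifier training in shallow / fine / deep tuning modes, prediction,
# and composition of sub-class probabilities back to the original classes.
#
# The built-in backbone ("small_cnn") is a 2-block CNN sized for desk-scale
# images; a trained classifier (e.g. the pretext model) can be passed as
# the backbone instead, in which case its convolutional body is reused and
# the classification head is discarded and re-initialised for the new
# label space.

#' Tuning-mode configuration
#'
#' \code{mode} selects what trains: \code{"shallow"} trains only the
#' classification head, \code{"deep"} trains everything, and
#' \code{"fine"} unfreezes the top \code{trainableLayers} parameterised
#' body layers plus the head. Defaults follow the downstream settings of
#' the method: learning rate 1e-4 for body layers and 0.01 for the head,
#' stepped down by 0.95 every 5 epochs, momentum 0.9, weight decay 0.01,
#' mini-batches of 50 and 50 epochs.
#'
#' @param mode \code{"shallow"}, \code{"fine"} or \code{"deep"}.
#' @param trainableLayers top body layers unfrozen in fine mode.
#' @param lrBody,lrHead learning rates for body and head parameter groups.
#' @param dropFactor,dropEvery step-decay schedule (factor per period).
#' @param batchSize,epochs mini-batch size and epoch count.
#' @param momentum,weightDecay SGD momentum and L2 penalty.
#' @param seed integer seed (init, batching).
#' @return A list of class \code{"TuneConfig"}.
#' @export
tuneConfig <- function(mode = c("fine", "shallow", "deep"),
                       trainableLayers = 1L, lrBody = 1e-4, lrHead = 0.01,
                       dropFactor = 0.95, dropEvery = 5L, batchSize = 50L,
                       epochs = 50L, momentum = 0.9, weightDecay = 0.01,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(trainableLayers >= 0L, lrBody > 0, lrHead > 0,
            dropFactor > 0, dropFactor <= 1, dropEvery >= 1L,
            batchSize >= 1L, epochs >= 1L, momentum >= 0, momentum < 1,
            weightDecay >= 0)
  structure(list(mode = mode, trainableLayers = as.integer(trainableLayers),
                 lrBody = lrBody, lrHead = lrHead, dropFactor = dropFactor,
                 dropEvery = as.integer(dropEvery),
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), momentum = momentum,
                 weightDecay = weightDecay, seed = as.integer(seed)),
            class = "TuneConfig")
}

# small CNN: conv(3,f1)-relu-pool2-conv(3,f2)-relu-pool2-fc(hidden)-relu-fc
.buildSmallCNN <- function(inputShape, nClasses, filters = c(8L, 16L),
                           hidden = 32L) {
  stopifnot(inputShape[1L] %% 4L == 0L, inputShape[2L] %% 4L == 0L)
  layers <- list(
    .convLayer("conv1", 3L, inputShape[3L], filters[1L], group = "body"),
    .reluLayer("relu1"),
    .poolLayer("pool1"),
    .convLayer("conv2", 3L, filters[1L], filters[2L], group = "body"),
    .reluLayer("relu2"),
    .poolLayer("pool2"),
    .flattenLayer("flatten"),
    .denseLayer("fc1", inputShape[1L] %/% 4L * (inputShape[2L] %/% 4L) *
                  filters[2L], hidden, group = "body"),
    .reluLayer("relu_fc1"),
    .denseLayer("logits", hidden, nClasses, group = "head"))
  .makeNet(layers, inputShape)
}

.applyFreezing <- function(net, config) {
  paramIdx <- which(vapply(net$layers, function(l)
    l$type %in% c("conv", "dense"), logical(1)))
  bodyIdx <- paramIdx[vapply(net$layers[paramIdx], function(l)
    !identical(l$group, "head"), logical(1))]
  frozen <- switch(config$mode,
    shallow = bodyIdx,
    deep = integer(0),
    fine = if (config$trainableLayers >= length(bodyIdx)) integer(0)
           else utils::head(bodyIdx,
                            length(bodyIdx) - config$trainableLayers))
  for (i in paramIdx) net$layers[[i]]$frozen <- FALSE
  for (i in frozen) net$layers[[i]]$frozen <- TRUE
  net
}

#' Train a classifier on a labelled image set
#'
#' Minimises softmax cross-entropy by momentum SGD with per-group learning
#' rates and a step-decay schedule, honouring the freezing pattern of the
#' tuning mode. Training uses the \code{train} split; when a \code{val}
#' split is present the returned model carries the parameters of the epoch
#' with the best validation accuracy. Deterministic given
#' \code{config$seed}.
#'
#' @param dataset a [LabeledImageSet-class] with >= 2 classes and a train
#'   split; every class must appear in the training split.
#' @param backbone \code{"small_cnn"} or a trained \code{"CNNClassifier"}
#'   whose body is reused (its head is discarded and re-initialised for
#'   the dataset's label space).
#' @param config a [tuneConfig()].
#' @param filters,hidden small-CNN width settings (ignored when a trained
#'   backbone is supplied).
#' @param composeWith optional [DecompositionMap-class]: when the dataset
#'   carries sub-class labels, epoch selection uses the validation
#'   accuracy of the composed parent-level prediction (the quantity the
#'   model is ultimately evaluated on) instead of raw sub-class accuracy.
#' @return A \code{"CNNClassifier"}: list with \code{net},
#'   \code{classNames}, \code{config}, \code{history}, \code{valAcc},
#'   \code{bestEpoch}.
#' @export
trainClassifier <- function(dataset, backbone = "small_cnn",
                            config = tuneConfig(), filters = c(8L, 16L),
                            hidden = 32L, composeWith = NULL) {
  cn <- classNames(dataset)
  if (length(cn) < 2L) stop("need at least 2 classes")
  if (!length(splitTags(dataset)))
    stop("dataset has no split; call assignSplits() first")
  trainIdx <- which(splitTags(dataset) == "train")
  valIdx <- which(splitTags(dataset) == "val")
  trainLabs <- imageLabels(dataset)[trainIdx]
  absent <- setdiff(seq_along(cn) - 1L, unique(trainLabs))
  if (length(absent))
    stop(sprintf("class(es) absent from the training split: %s",
                 paste(cn[absent + 1L], collapse = ", ")))
  inputShape <- dim(images(dataset))[1:3]
  set.seed(config$seed)
  if (inherits(backbone, "CNNClassifier")) {
    net <- backbone$net
    if (!identical(net$inputShape, inputShape))
      stop("backbone input shape does not match the dataset")
    # discard the old head; fresh head for the new label space
    hi <- .layerIndex(net, "logits")
    din <- nrow(net$layers[[hi]]$W)
    net$layers[[hi]] <- .denseLayer("logits", din, length(cn),
                                    group = "head")
    net <- .makeNet(net$layers, inputShape)
  } else if (identical(backbone, "small_cnn")) {
    net <- .buildSmallCNN(inputShape, length(cn), filters, hidden)
  } else stop("backbone must be \"small_cnn\" or a CNNClassifier")
  net <- .applyFreezing(net, config)
  X <- .flattenImages(images(dataset)[, , , trainIdx, drop = FALSE]) -
    .IMG_CENTER
  y <- trainLabs
  hasVal <- length(valIdx) > 0L
  Xval <- if (hasVal)
    .flattenImages(images(dataset)[, , , valIdx, drop = FALSE]) -
      .IMG_CENTER else NULL
  valGroups <- NULL
  yval <- if (hasVal) imageLabels(dataset)[valIdx] else NULL
  if (hasVal && !is.null(composeWith)) {
    parents <- names(childrenOf(composeWith))
    valGroups <- match(unname(parentOf(composeWith)[cn]), parents) - 1L
    yval <- valGroups[yval + 1L]
  }
  fit <- .trainNet(net, X, y, loss = "ce", epochs = config$epochs,
                   batchSize = config$batchSize, lrBody = config$lrBody,
                   lrHead = config$lrHead, momentum = config$momentum,
                   weightDecay = config$weightDecay,
                   dropFactor = config$dropFactor,
                   dropEvery = config$dropEvery, seed = config$seed,
                   Xval = Xval, yval = yval,
                   selectBest = hasVal, valGroups = valGroups)
  structure(list(net = fit$net, classNames = cn, config = config,
                 history = fit$history, valAcc = fit$valAcc,
                 bestEpoch = fit$bestEpoch, inputShape = inputShape),
            class = "CNNClassifier")
}

#' @export
print.CNNClassifier <- function(x, ...) {
  cat(sprintf("CNNClassifier: %s input, %d classes (%s), mode '%s'\n",
              paste(x$inputShape, collapse = "x"), length(x$classNames),
              paste(x$classNames, collapse = ", "), x$config$mode))
  if (!is.null(x$valAcc))
    cat(sprintf("  best val accuracy %.3f at epoch %d\n",
                max(x$valAcc), x$bestEpoch))
  invisible(x)
}

#' Layer names of a model
#'
#' @param model a \code{"CNNClassifier"} or \code{"CAEModel"}.
#' @return Character vector of layer names, in forward order.
#' @export
availableLayers <- function(model) model$net$layerNames

#' Predict class probabilities
#'
#' Softmax over the model logits, one row per image in dataset order.
#'
#' @param model a trained \code{"CNNClassifier"}.
#' @param dataset a [LabeledImageSet-class] whose label space matches the
#'   model's.
#' @return A [ProbabilityTable-class] with the dataset labels as truth.
#' @export
predictProbs <- function(model, dataset) {
  d <- dim(images(dataset))[1:3]
  if (!identical(d, model$inputShape))
    stop(sprintf("image dims %s do not match model input dims %s",
                 paste(d, collapse = "x"),
                 paste(model$inputShape, collapse = "x")))
  X <- .flattenImages(images(dataset)) - .IMG_CENTER
  P <- .softmax(.nnForward(model$net, X)$out)
  colnames(P) <- model$classNames
  ProbabilityTable(P, imageLabels(dataset))
}

#' Compose sub-class probabilities into parent-class probabilities
#'
#' The composition (error-correction) stage: a parent class's probability
#' is the sum of its children's probabilities, so rows remain stochastic
#' and the predicted parent is the argmax (lowest index on ties). Truth
#' codes are relabelled from sub-classes to parents.
#'
#' @param subProbs a [ProbabilityTable-class] over sub-class labels.
#' @param map the [DecompositionMap-class] that generated the sub-classes.
#' @return A [ProbabilityTable-class] over the parent classes, in
#'   \code{childrenOf(map)} order.
#' @examples
#' m <- new("DecompositionMap",
#'          parentOf = c(c0_0 = "c0", c0_1 = "c0", c1_0 = "c1"),
#'          childrenOf = list(c0 = c("c0_0", "c0_1"), c1 = "c1_0"),
#'          assignment = c("c0_0", "c0_1", "c1_0"), method = "ap")
#' p <- ProbabilityTable(matrix(c(0.4, 0.3, 0.3), 1, 3,
#'                       dimnames = list(NULL, c("c0_0", "c0_1", "c1_0"))),
#'                       truth = 0L)
#' composeProbs(p, m)@probs  # 0.7, 0.3
#' @export
composeProbs <- function(subProbs, map) {
  subNames <- colnames(subProbs@probs)
  known <- names(parentOf(map))
  missing <- setdiff(subNames, known)
  if (length(missing))
    stop(sprintf("sub-label(s) missing from the map: %s",
                 paste(missing, collapse = ", ")))
  parents <- names(childrenOf(map))
  P <- matrix(0, nrow(subProbs@probs), length(parents),
              dimnames = list(NULL, parents))
  for (p in parents) {
    ch <- intersect(childrenOf(map)[[p]], subNames)
    P[, p] <- rowSums(subProbs@probs[, ch, drop = FALSE])
  }
  truthParent <- match(unname(parentOf(map)[subNames[subProbs@truth + 1L]]),
                       parents) - 1L
  ProbabilityTable(P, truthParent)
}
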