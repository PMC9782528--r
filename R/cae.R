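#' Convolutional autoencoder configuration
#'
#' Hyperparameters for the unsupervised feature extractor used in the
#' pretext stage. The encoder stacks \code{nConvBlocks} blocks of
#' (convolution, rectifier, max-pool); the decoder mirrors them with
#' nearest-neighbour upsampling followed by convolution, ending in a linear
#' reconstruction layer. Kernels are square with side \code{2f + 1} where
#' \code{f = kernelHalfWidth}. Defaults follow the histology setting of the
#' method: two blocks of 64 and 32 filters, 3x3 kernels, learning rate
#' 0.001, mini-batches of 128 and 100 epochs (use \code{filtersPerBlock =
#' c(32, 16)} for single-channel MRI-like data); desk-scale fixtures
#' override them downwards.
#'
#' @param nConvBlocks number of encoder blocks.
#' @param filtersPerBlock integer vector, one filter count per block.
#' @param kernelHalfWidth f such that the kernel side is 2f+1 (default 1,
#'   i.e. 3x3).
#' @param activation elementwise nonlinearity; only \code{"relu"} is
#'   provided.
#' @param poolFactor spatial downsampling per block.
#' @param learningRate,batchSize,epochs SGD settings.
#' @param momentum SGD momentum.
#' @param tiedWeights logical; when \code{TRUE} decoder kernels are the
#'   spatially flipped, channel-swapped encoder kernels (shared
#'   parameters); default \code{FALSE} learns the decoder independently.
#' @param seed integer seed controlling initialisation and batching.
#' @return A list of class \code{"CAEConfig"}.
#' @export
caeConfig <- function(nConvBlocks = 2L, filtersPerBlock = c(64L, 32L),
                      kernelHalfWidth = 1L, activation = "relu",
                      poolFactor = 2L, learningRate = 0.001,
                      batchSize = 128L, epochs = 100L, momentum = 0.9,
                      tiedWeights = FALSE, seed = 1L) {
  stopifnot(nConvBlocks >= 1L, all(filtersPerBlock >= 1L),
            kernelHalfWidth >= 1L, poolFactor >= 1L, learningRate > 0,
            batchSize >= 1L, epochs >= 1L)
  if (length(filtersPerBlock) != nConvBlocks)
    stop("length(filtersPerBlock) must equal nConvBlocks")
  if (!identical(activation, "relu"))
    stop("only the rectifier activation is implemented")
  structure(list(nConvBlocks = as.integer(nConvBlocks),
                 filtersPerBlock = as.integer(filtersPerBlock),
                 kernelHalfWidth = as.integer(kernelHalfWidth),
                 activation = activation,
                 poolFactor = as.integer(poolFactor),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), momentum = momentum,
                 tiedWeights = isTRUE(tiedWeights), seed = as.integer(seed)),
            class = "CAEConfig")
}

.buildCAE <- function(inputShape, config) {
  k <- 2L * config$kernelHalfWidth + 1L
  f <- config$poolFactor
  B <- config$nConvBlocks
  filt <- config$filtersPerBlock
  cin <- inputShape[3L]
  layers <- list()
  chans <- c(cin, filt)
  for (b in seq_len(B)) {
    layers <- c(layers, list(
      .convLayer(sprintf("enc_conv%d", b), k, chans[b], chans[b + 1L]),
      .reluLayer(sprintf("enc_relu%d", b)),
      .poolLayer(sprintf("enc_pool%d", b), f)))
  }
  encIdx <- length(layers)
  for (b in rev(seq_len(B))) {
    last <- b == 1L
    conv <- .convLayer(sprintf("dec_conv%d", B - b + 1L), k, chans[b + 1L],
                       chans[b])
    if (config$tiedWeights) conv$tiedTo <- (b - 1L) * 3L + 1L
    layers <- c(layers, list(
      .upsampleLayer(sprintf("dec_up%d", B - b + 1L), f), conv))
    if (!last)
      layers <- c(layers, list(.reluLayer(sprintf("dec_relu%d", B - b + 1L))))
  }
  list(layers = layers, encIdx = encIdx)
}

#' Train a convolutional autoencoder
#'
#' Fits the encoder/decoder by mini-batch SGD on the mean-squared
#' reconstruction error \eqn{MSE(\theta) = \frac{1}{2n}\sum_i \|x_i -
#' \hat{x}_i\|^2}. The loss history holds the full-training-set MSE after
#' each epoch, so its final entry is exactly the MSE of
#' [reconstructImages()] on the training images.
#'
#' @param imageSet a [LabeledImageSet-class] (labels are ignored; this is
#'   the unsupervised pretext stage).
#' @param config a [caeConfig()] object.
#' @return A list of class \code{"CAEModel"} with elements \code{net},
#'   \code{config}, \code{latentShape}, \code{inputShape} and
#'   \code{lossHistory}.
#' @examples
#' pool <- generateUnlabeled(syntheticSpec(imageSide = 16, seed = 1),
#'                           nImages = 40, nModes = 2)
#' cae <- trainCAE(pool, caeConfig(filtersPerBlock = c(4, 2),
#'                                 batchSize = 20, epochs = 2))
#' tail(cae$lossHistory, 1)
#' @export
trainCAE <- function(imageSet, config = caeConfig()) {
  d <- dim(images(imageSet))
  if (d[1L] != d[2L]) stop("images must be square")
  if (d[4L] < config$batchSize)
    config$batchSize <- d[4L]
  inputShape <- d[1:3]
  red <- config$poolFactor^config$nConvBlocks
  if (d[1L] %% red != 0L)
    stop(sprintf("image side %d not divisible by total pooling factor %d",
                 d[1L], red))
  latentShape <- c(d[1L] / red, d[2L] / red,
                   config$filtersPerBlock[config$nConvBlocks])
  if (prod(latentShape) >= prod(inputShape))
    stop(sprintf(
      "latent dimensionality %d is not a compression of the %d input pixels; reduce filters or add blocks",
      prod(latentShape), prod(inputShape)))
  set.seed(config$seed)
  arch <- .buildCAE(inputShape, config)
  net <- .makeNet(arch$layers, inputShape)
  if (config$tiedWeights) net <- .sgdStep(net, vector("list",
                                          length(net$layers)),
                                          0, 0, 0, 0)  # initial sync
  X <- .flattenImages(images(imageSet)) - .IMG_CENTER
  fit <- .trainNet(net, X, X, loss = "mse", epochs = config$epochs,
                   batchSize = config$batchSize,
                   lrBody = config$learningRate,
                   momentum = config$momentum, seed = config$seed)
  structure(list(net = fit$net, config = config, encIdx = arch$encIdx,
                 latentShape = latentShape, inputShape = inputShape,
                 lossHistory = fit$history),
            class = "CAEModel")
}

#' Encode images into the CAE latent space
#'
#' Runs the encoder half of a trained (or freshly initialised) CAE and
#' flattens the post-pooling activation maps of the last block into one row
#' per image.
#'
#' @param model a \code{"CAEModel"} from [trainCAE()].
#' @param imageSet a [LabeledImageSet-class] with the training dimensions.
#' @return A [FeatureMatrix-class] with source \code{"cae_latent"}.
#' @export
encodeImages <- function(model, imageSet) {
  d <- dim(images(imageSet))
  if (!identical(d[1:3], model$inputShape))
    stop(sprintf("image dims %s do not match model input dims %s",
                 paste(d[1:3], collapse = "x"),
                 paste(model$inputShape, collapse = "x")))
  X <- .flattenImages(images(imageSet)) - .IMG_CENTER
  encNet <- .makeNet(model$net$layers[seq_len(model$encIdx)],
                     model$inputShape)
  Z <- .nnForward(encNet, X)$out
  FeatureMatrix(Z, source = "cae_latent")
}

#' Reconstruct images through the autoencoder
#'
#' @param model a \code{"CAEModel"}.
#' @param imageSet images with the training dimensions.
#' @param clip clamp intensities into [0, 1] (for visualisation); set
#'   \code{FALSE} to obtain the raw decoder output used by the loss.
#' @return An array with the same dimensions as \code{images(imageSet)}.
#' @export
reconstructImages <- function(model, imageSet, clip = TRUE) {
  d <- dim(images(imageSet))
  if (!identical(d[1:3], model$inputShape))
    stop(sprintf("image dims %s do not match model input dims %s",
                 paste(d[1:3], collapse = "x"),
                 paste(model$inputShape, collapse = "x")))
  X <- .flattenImages(images(imageSet)) - .IMG_CENTER
  Xhat <- .nnForward(model$net, X)$out + .IMG_CENTER
  if (clip) Xhat <- pmin(pmax(Xhat, 0), 1)
  .unflattenImages(Xhat, model$inputShape)
}

#' @export
print.CAEModel <- function(x, ...) {
  cat(sprintf(
    "CAEModel: %s input -> %s latent (%d dims), %d epoch(s), final MSE %.5g\n",
    paste(x$inputShape, collapse = "x"),
    paste(x$latentShape, collapse = "x"), prod(x$latentShape),
    length(x$lossHistory), utils::tail(x$lossHistory, 1)))
  invisible(x)
}
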