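# Grad-CAM post-hoc attention maps. The class score is the pre-softmax
# logit (the usual Grad-CAM convention; softmax gradients saturate), the
# per-map weight is the spatial mean of its gradient, and the heatmap is
# the rectified weighted sum of activation maps, upsampled bilinearly to
# the input grid and min-max normalised.

.bilinearUpsample <- function(M, H, W) {
  h <- nrow(M); w <- ncol(M)
  if (h == H && w == W) return(M)
  ri <- if (H == 1L) rep(1, H) else (seq_len(H) - 1) * (h - 1) / (H - 1) + 1
  ci <- if (W == 1L) rep(1, W) else (seq_len(W) - 1) * (w - 1) / (W - 1) + 1
  r0 <- pmin(floor(ri), h - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(ci), w - 1L); c0 <- pmax(c0, 1L)
  if (h == 1L) { r0 <- rep(1L, H); fr <- rep(0, H) } else fr <- ri - r0
  if (w == 1L) { c0 <- rep(1L, W); fc <- rep(0, W) } else fc <- ci - c0
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  out <- matrix(0, H, W)
  for (j in seq_len(W)) {
    a <- M[r0, c0[j]] * (1 - fr) + M[r1, c0[j]] * fr
    b <- M[r0, c1[j]] * (1 - fr) + M[r1, c1[j]] * fr
    out[, j] <- a * (1 - fc[j]) + b * fc[j]
  }
  out
}

.asSingleImage <- function(image, inputShape) {
  if (is(image, "LabeledImageSet")) {
    if (nImages(image) != 1L)
      stop("pass a single image (or subset the set to one image)")
    image <- images(image)[, , , 1L, drop = TRUE]
  }
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  if (!identical(dim(image), as.integer(inputShape)) &&
      !identical(dim(image), inputShape))
    stop(sprintf("image dims %s do not match model input dims %s",
                 paste(dim(image), collapse = "x"),
                 paste(inputShape, collapse = "x")))
  image
}

#' Grad-CAM heatmap for one image and class
#'
#' Computes the gradient of the pre-softmax score of \code{targetClass}
#' with respect to the named convolutional activation, pools it spatially
#' into one weight per feature map (\eqn{\phi_d = \frac{1}{m}\sum_{ij}
#' \partial x_c / \partial A^d_{ij}}), and rectifies the weighted sum
#' \eqn{ReLU(\sum_d \phi_d A^d)} into a non-negative map, upsampled
#' bilinearly to the input grid and min-max normalised to [0, 1]. A map
#' that is identically zero after rectification is returned as all zeros
#' with a warning.
#'
#' @param model a trained \code{"CNNClassifier"}.
#' @param image a single image: h x w (x c) array, or a one-image
#'   [LabeledImageSet-class].
#' @param targetClass 0-based class code or class name.
#' @param layer convolutional activation layer; default the last
#'   convolutional activation of the network.
#' @return A [GradCAMResult-class].
#' @export
gradCAM <- function(model, image, targetClass, layer = NULL) {
  stopifnot(inherits(model, "CNNClassifier"))
  net <- model$net
  if (is.null(layer)) layer <- .lastConvActivation(net)
  li <- .layerIndex(net, layer)
  shape <- net$shapes[[li + 1L]]
  if (length(shape) != 3L)
    stop(sprintf("layer '%s' has no spatial dimensions", layer))
  if (is.character(targetClass))
    targetClass <- match(targetClass, model$classNames) - 1L
  targetClass <- as.integer(targetClass)
  if (is.na(targetClass) || targetClass < 0L ||
      targetClass >= length(model$classNames))
    stop("unknown target class")
  img <- .asSingleImage(image, model$inputShape)
  X <- matrix(as.vector(img), 1L) - .IMG_CENTER
  fwd <- .nnForward(net, X, keep = TRUE)
  K <- length(model$classNames)
  dOut <- matrix(0, 1L, K)
  dOut[1L, targetClass + 1L] <- 1      # d logit_c / d logits
  bk <- .nnBackward(net, fwd, dOut, stopAt = layer)
  H <- shape[1L]; W <- shape[2L]; C <- shape[3L]
  A <- array(fwd$acts[[li + 1L]][1L, ], c(H, W, C))
  G <- array(bk$dAt[1L, ], c(H, W, C))
  phi <- apply(G, 3L, mean)            # 1/m sum_ij gradient, per map
  raw <- matrix(0, H, W)
  for (d in seq_len(C)) raw <- raw + phi[d] * A[, , d]
  raw <- pmax(raw, 0)
  if (max(raw) == 0)
    warning("rectified class-attention map is identically zero")
  up <- .bilinearUpsample(raw, dim(img)[1L], dim(img)[2L])
  heat <- if (max(up) > 0) (up - min(up)) / (max(up) - min(up))
          else up
  new("GradCAMResult", weights = phi, rawMap = raw, heatmap = heat,
      targetClass = targetClass, layer = layer, children = list())
}

.lastConvActivation <- function(net) {
  convIdx <- which(vapply(net$layers, function(l) l$type == "conv",
                          logical(1)))
  li <- max(convIdx)
  # prefer the rectified activation directly after the conv, if present
  if (li < length(net$layers) && net$layers[[li + 1L]]$type == "relu")
    net$layers[[li + 1L]]$name
  else net$layers[[li]]$name
}

#' Composed-class Grad-CAM over a decomposition
#'
#' For a model trained on sub-class labels, computes [gradCAM()] for every
#' child of \code{parentClass} and combines the children's raw maps by
#' element-wise maximum (so any child's evidence is preserved), then
#' normalises. The per-child results are kept in the \code{children} slot.
#'
#' @param model sub-class-level \code{"CNNClassifier"}.
#' @param image single image as in [gradCAM()].
#' @param parentClass parent class name.
#' @param map the [DecompositionMap-class].
#' @param layer convolutional activation layer (default as [gradCAM()]).
#' @return A [GradCAMResult-class] (targetClass is the first child's code).
#' @export
explainComposed <- function(model, image, parentClass, map, layer = NULL) {
  ch <- childrenOf(map)[[parentClass]]
  if (is.null(ch) || !length(ch))
    stop(sprintf("parent class '%s' has no children in the map",
                 parentClass))
  kids <- lapply(ch, function(s) {
    code <- match(s, model$classNames) - 1L
    if (is.na(code))
      stop(sprintf("sub-label '%s' is not a model class", s))
    gradCAM(model, image, code, layer = layer)
  })
  raw <- Reduce(pmax, lapply(kids, function(k) k@rawMap))
  img <- .asSingleImage(image, model$inputShape)
  up <- .bilinearUpsample(raw, dim(img)[1L], dim(img)[2L])
  heat <- if (max(up) > 0) (up - min(up)) / (max(up) - min(up)) else up
  names(kids) <- ch
  new("GradCAMResult", weights = kids[[1L]]@weights, rawMap = raw,
      heatmap = heat, targetClass = kids[[1L]]@targetClass,
      layer = kids[[1L]]@layer, children = kids)
}

#' Write a heatmap overlay PNG
#'
#' Alpha-blends a jet-style colouring of the normalised heatmap over the
#' (grayscale or RGB) image, with blend weight 0.4, and writes a lossless
#' PNG: strong attention shows red/yellow, weak attention blue.
#'
#' @param image the input image (h x w (x c) array or one-image set).
#' @param result a [GradCAMResult-class] for that image.
#' @param outPath output PNG path.
#' @param alpha heatmap blend weight.
#' @return \code{outPath}, invisibly.
#' @export
overlayHeatmap <- function(image, result, outPath, alpha = 0.4) {
  if (is(image, "LabeledImageSet")) image <- images(image)[, , , 1L]
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  if (!identical(dim(result@heatmap), c(H, W)))
    stop("heatmap does not match the image grid")
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "cyan", "yellow",
                                 "red", "#7F0000"))
  cols <- ramp(as.vector(result@heatmap)) / 255
  rgb <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    base <- if (dim(image)[3L] == 3L) image[, , ch] else image[, , 1L]
    rgb[, , ch] <- (1 - alpha) * base + alpha * matrix(cols[, ch], H, W)
  }
  dir.create(dirname(outPath), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({png::writePNG(rgb, outPath); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(outPath))
    stop(sprintf("cannot write overlay to '%s'", outPath))
  invisible(outPath)
}
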