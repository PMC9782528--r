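# Internal mini neural-network engine.
#
# Activations are matrices of shape n x (H*W*C); per-sample layout follows R
# array order of an H x W x C array (row index fastest, then column, then
# channel). Convolution is the usual cross-correlation with "same"
# zero-padding, evaluated as im2col + BLAS matmul; kernel flipping is
# absorbed into the learned weights. Pooling is 2x2 (or f x f) max with
# first-claim tie-breaking, upsampling nearest-neighbour. All randomness is
# routed through an explicit seed so forward/backward and training are
# bit-reproducible.

.flattenImages <- function(imgs) {
  d <- dim(imgs)                      # H x W x C x n
  t(matrix(imgs, d[1L] * d[2L] * d[3L], d[4L]))
}

.unflattenImages <- function(X, shape) {
  n <- nrow(X)
  array(t(X), c(shape, n))
}

.initUniform <- function(n, fanIn) {
  lim <- sqrt(6 / fanIn)
  stats::runif(n, -lim, lim)
}

# images are stored in [0,1]; nets see them centred at zero (the shift is
# undone where reconstructions are returned)
.IMG_CENTER <- 0.5

# weight array (k,k,cin,cout) <-> storage matrix ((k*k*cin) x cout) whose row
# order is (du fastest, dv, cin), matching the im2col column order below
.convWeightMat <- function(Warr) {
  k <- dim(Warr)[1L]; cin <- dim(Warr)[3L]; cout <- dim(Warr)[4L]
  # im2col blocks are (du,dv) outer, cin inner: column = ((dv-1)k+(du-1))cin+c
  m <- matrix(0, k * k * cin, cout)
  for (dv in seq_len(k)) for (du in seq_len(k)) for (ci in seq_len(cin))
    m[((dv - 1L) * k + (du - 1L)) * cin + ci, ] <- Warr[du, dv, ci, ]
  m
}

.convLayer <- function(name, k, cin, cout, group = "body", seed = NULL,
                       Warr = NULL, b = NULL, linear = FALSE) {
  if (is.null(Warr)) {
    W <- matrix(.initUniform(k * k * cin * cout, k * k * cin),
                k * k * cin, cout)
  } else W <- .convWeightMat(Warr)
  if (is.null(b)) b <- numeric(cout)
  list(name = name, type = "conv", W = W, b = b, k = k, cin = cin,
       cout = cout, group = group, frozen = FALSE,
       vW = W * 0, vb = b * 0)
}

.denseLayer <- function(name, din, dout, group = "head", seed = NULL,
                        W = NULL, b = NULL) {
  if (is.null(W)) W <- matrix(.initUniform(din * dout, din), din, dout)
  if (is.null(b)) b <- numeric(dout)
  list(name = name, type = "dense", W = W, b = b, group = group,
       frozen = FALSE, vW = W * 0, vb = b * 0)
}

.reluLayer <- function(name) list(name = name, type = "relu")
.poolLayer <- function(name, f = 2L) list(name = name, type = "pool", f = f)
.upsampleLayer <- function(name, f = 2L)
  list(name = name, type = "upsample", f = f)
.flattenLayer <- function(name) list(name = name, type = "flatten")

# shape propagation; shape = c(H, W, C) or scalar d for flat activations
.outShape <- function(layer, shape) {
  switch(layer$type,
    conv = c(shape[1L], shape[2L], layer$cout),
    relu = shape,
    pool = {
      stopifnot(shape[1L] %% layer$f == 0L, shape[2L] %% layer$f == 0L)
      c(shape[1L] / layer$f, shape[2L] / layer$f, shape[3L])
    },
    upsample = c(shape[1L] * layer$f, shape[2L] * layer$f, shape[3L]),
    flatten = prod(shape),
    dense = ncol(layer$W))
}

.netShapes <- function(layers, inputShape) {
  shapes <- vector("list", length(layers) + 1L)
  shapes[[1L]] <- inputShape
  for (i in seq_along(layers))
    shapes[[i + 1L]] <- .outShape(layers[[i]], shapes[[i]])
  shapes
}

.im2col <- function(X, shape, k) {
  n <- nrow(X); H <- shape[1L]; W <- shape[2L]; C <- shape[3L]
  p <- (k - 1L) %/% 2L
  A <- array(0, c(n, H + 2L * p, W + 2L * p, C))
  A[, p + seq_len(H), p + seq_len(W), ] <- array(t(X), c(H, W, C, n)) |>
    aperm(c(4L, 1L, 2L, 3L))
  cols <- matrix(0, n * H * W, k * k * C)
  blk <- 0L
  for (dv in seq_len(k)) for (du in seq_len(k)) {
    S <- A[, du:(du + H - 1L), dv:(dv + W - 1L), , drop = FALSE]
    cols[, blk + seq_len(C)] <- matrix(S, n * H * W, C)
    blk <- blk + C
  }
  cols
}

.col2im <- function(dcols, shape, k, n) {
  H <- shape[1L]; W <- shape[2L]; C <- shape[3L]
  p <- (k - 1L) %/% 2L
  dA <- array(0, c(n, H + 2L * p, W + 2L * p, C))
  blk <- 0L
  for (dv in seq_len(k)) for (du in seq_len(k)) {
    B <- array(dcols[, blk + seq_len(C)], c(n, H, W, C))
    dA[, du:(du + H - 1L), dv:(dv + W - 1L), ] <-
      dA[, du:(du + H - 1L), dv:(dv + W - 1L), , drop = FALSE] + B
    blk <- blk + C
  }
  Dc <- dA[, p + seq_len(H), p + seq_len(W), , drop = FALSE]
  matrix(aperm(Dc, c(2L, 3L, 4L, 1L)), n, H * W * C, byrow = TRUE)
}

.forwardLayer <- function(layer, X, shape, keep = FALSE) {
  n <- nrow(X)
  switch(layer$type,
    conv = {
      cols <- .im2col(X, shape, layer$k)
      out <- cols %*% layer$W
      out <- sweep(out, 2L, layer$b, "+")
      list(out = matrix(as.vector(out), n, shape[1L] * shape[2L] * layer$cout),
           cache = if (keep) cols else NULL)
    },
    relu = list(out = pmax(X, 0), cache = NULL),
    pool = {
      f <- layer$f; H <- shape[1L]; W <- shape[2L]; C <- shape[3L]
      A <- array(t(X), c(H, W, C, n))
      Ho <- H %/% f; Wo <- W %/% f
      P <- array(-Inf, c(Ho, Wo, C, n))
      for (dv in seq_len(f)) for (du in seq_len(f)) {
        S <- A[seq(du, H, f), seq(dv, W, f), , , drop = FALSE]
        P <- pmax(P, S)
      }
      list(out = t(matrix(P, Ho * Wo * C, n)), cache = NULL)
    },
    upsample = {
      f <- layer$f; H <- shape[1L]; W <- shape[2L]; C <- shape[3L]
      A <- array(t(X), c(H, W, C, n))
      U <- A[rep(seq_len(H), each = f), rep(seq_len(W), each = f), , ,
             drop = FALSE]
      list(out = t(matrix(U, H * f * W * f * C, n)), cache = NULL)
    },
    flatten = list(out = X, cache = NULL),
    dense = list(out = sweep(X %*% layer$W, 2L, layer$b, "+"), cache = NULL))
}

# Full forward pass; returns every layer's input (acts[[i]] feeds layer i)
# and output, so the same cache serves training, feature extraction and
# Grad-CAM capture.
.nnForward <- function(net, X, keep = FALSE) {
  L <- length(net$layers)
  acts <- vector("list", L + 1L)
  caches <- vector("list", L)
  acts[[1L]] <- X
  for (i in seq_len(L)) {
    fl <- .forwardLayer(net$layers[[i]], acts[[i]], net$shapes[[i]], keep)
    acts[[i + 1L]] <- fl$out
    caches[[i]] <- fl$cache
  }
  list(out = acts[[L + 1L]], acts = acts, caches = caches)
}

.backwardLayer <- function(layer, d, Xin, Xout, shape, cache) {
  n <- nrow(d)
  switch(layer$type,
    conv = {
      H <- shape[1L]; W <- shape[2L]
      dmat <- matrix(as.vector(d), n * H * W, layer$cout)
      cols <- if (is.null(cache)) .im2col(Xin, shape, layer$k) else cache
      dW <- crossprod(cols, dmat)
      db <- colSums(dmat)
      dcols <- dmat %*% t(layer$W)
      list(dX = .col2im(dcols, shape, layer$k, n), dW = dW, db = db)
    },
    relu = list(dX = d * (Xin > 0)),
    pool = {
      f <- layer$f; H <- shape[1L]; W <- shape[2L]; C <- shape[3L]
      A <- array(t(Xin), c(H, W, C, n))
      Ho <- H %/% f; Wo <- W %/% f
      P <- array(t(Xout), c(Ho, Wo, C, n))
      D <- array(t(d), c(Ho, Wo, C, n))
      dA <- array(0, c(H, W, C, n))
      claimed <- array(FALSE, c(Ho, Wo, C, n))
      for (dv in seq_len(f)) for (du in seq_len(f)) {
        S <- A[seq(du, H, f), seq(dv, W, f), , , drop = FALSE]
        m <- (S == P) & !claimed
        claimed <- claimed | m
        dA[seq(du, H, f), seq(dv, W, f), , ] <-
          dA[seq(du, H, f), seq(dv, W, f), , , drop = FALSE] + D * m
      }
      list(dX = t(matrix(dA, H * W * C, n)))
    },
    upsample = {
      f <- layer$f; Ho <- shape[1L]; Wo <- shape[2L]; C <- shape[3L]
      D <- array(t(d), c(Ho * f, Wo * f, C, n))
      dA <- array(0, c(Ho, Wo, C, n))
      for (dv in seq_len(f)) for (du in seq_len(f))
        dA <- dA + D[seq(du, Ho * f, f), seq(dv, Wo * f, f), , ,
                     drop = FALSE]
      list(dX = t(matrix(dA, Ho * Wo * C, n)))
    },
    flatten = list(dX = d),
    dense = list(dX = d %*% t(layer$W), dW = crossprod(Xin, d),
                 db = colSums(d)))
}

# Backprop dOut (gradient w.r.t. final output) through the net; stops early
# and returns the running gradient when stopAt names a layer (gradient
# w.r.t. that layer's OUTPUT), otherwise returns per-layer parameter grads.
.nnBackward <- function(net, fwd, dOut, stopAt = NULL) {
  L <- length(net$layers)
  grads <- vector("list", L)
  d <- dOut
  for (i in rev(seq_len(L))) {
    layer <- net$layers[[i]]
    if (!is.null(stopAt) && identical(layer$name, stopAt))
      return(list(dAt = d, grads = grads))
    bl <- .backwardLayer(layer, d, fwd$acts[[i]], fwd$acts[[i + 1L]],
                         net$shapes[[i]], fwd$caches[[i]])
    grads[[i]] <- bl[c("dW", "db")]
    d <- bl$dX
  }
  if (!is.null(stopAt))
    stop(sprintf("layer '%s' not found; available: %s", stopAt,
                 paste(vapply(net$layers, `[[`, "", "name"),
                       collapse = ", ")))
  list(dInput = d, grads = grads)
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.makeNet <- function(layers, inputShape) {
  net <- list(layers = layers, inputShape = inputShape)
  net$shapes <- .netShapes(layers, inputShape)
  net$layerNames <- vapply(layers, `[[`, "", "name")
  net
}

.layerIndex <- function(net, name) {
  i <- match(name, net$layerNames)
  if (is.na(i))
    stop(sprintf("unknown layer '%s'; available layers: %s", name,
                 paste(net$layerNames, collapse = ", ")))
  i
}

.convWeightArr <- function(Wm, k, cin, cout) {
  A <- array(0, c(k, k, cin, cout))
  for (dv in seq_len(k)) for (du in seq_len(k)) for (ci in seq_len(cin))
    A[du, dv, ci, ] <- Wm[((dv - 1L) * k + (du - 1L)) * cin + ci, ]
  A
}

# decoder kernel tied to an encoder kernel: both spatial dims flipped and
# in/out channel roles swapped
.flipTiedKernel <- function(srcWm, k, cin, cout) {
  A <- .convWeightArr(srcWm, k, cin, cout)
  At <- aperm(A[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
  .convWeightMat(At)
}

# One SGD-with-momentum step; velocity v <- mom*v - lr*(g + wd*W).
# A conv layer with tiedTo = j shares (flipped) weights with layer j: its
# gradient is folded into layer j's and its kernel re-synced afterwards.
.sgdStep <- function(net, grads, lrBody, lrHead, momentum, weightDecay) {
  for (i in seq_along(net$layers)) {
    layer <- net$layers[[i]]
    if (is.null(layer$tiedTo) || is.null(grads[[i]]$dW)) next
    src <- net$layers[[layer$tiedTo]]
    dtied <- .flipTiedKernel(grads[[i]]$dW, layer$k, layer$cin, layer$cout)
    grads[[layer$tiedTo]]$dW <- grads[[layer$tiedTo]]$dW + dtied
  }
  for (i in seq_along(net$layers)) {
    layer <- net$layers[[i]]
    if (is.null(grads[[i]]) || is.null(grads[[i]]$dW) || isTRUE(layer$frozen))
      next
    if (!is.null(layer$tiedTo)) {
      # weights synced from the source below; bias still learned locally
      layer$vb <- momentum * layer$vb -
        (if (identical(layer$group, "head")) lrHead else lrBody) *
        grads[[i]]$db
      layer$b <- layer$b + layer$vb
      net$layers[[i]] <- layer
      next
    }
    lr <- if (identical(layer$group, "head")) lrHead else lrBody
    gW <- grads[[i]]$dW + weightDecay * layer$W
    layer$vW <- momentum * layer$vW - lr * gW
    layer$W <- layer$W + layer$vW
    layer$vb <- momentum * layer$vb - lr * grads[[i]]$db
    layer$b <- layer$b + layer$vb
    net$layers[[i]] <- layer
  }
  for (i in seq_along(net$layers)) {
    layer <- net$layers[[i]]
    if (is.null(layer$tiedTo)) next
    src <- net$layers[[layer$tiedTo]]
    net$layers[[i]]$W <- .flipTiedKernel(src$W, src$k, src$cin, src$cout)
  }
  net
}

.ceLossGrad <- function(logits, y) {
  # y: 0-based integer labels
  P <- .softmax(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dP <- P
  dP[idx] <- dP[idx] - 1
  list(loss = loss, grad = dP / n)
}

.mseLossGrad <- function(out, target) {
  n <- nrow(out)
  r <- out - target
  list(loss = sum(r * r) / (2 * n), grad = r / n)
}

# Generic mini-batch SGD trainer. loss = "ce" (y integer labels) or "mse"
# (y target matrix). Returns net, per-epoch loss history (evaluated on the
# full training set after each epoch for "mse"; running batch mean for
# "ce"), and optional per-epoch validation accuracy with best-epoch
# restoration.
.clipGrads <- function(grads, clipNorm) {
  if (!is.finite(clipNorm)) return(grads)
  tot <- 0
  for (g in grads)
    if (!is.null(g$dW)) tot <- tot + sum(g$dW^2) + sum(g$db^2)
  nrm <- sqrt(tot)
  if (nrm <= clipNorm) return(grads)
  sc <- clipNorm / nrm
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]]$dW)) next
    grads[[i]]$dW <- grads[[i]]$dW * sc
    grads[[i]]$db <- grads[[i]]$db * sc
  }
  grads
}

.trainNet <- function(net, X, y, loss = c("ce", "mse"), epochs, batchSize,
                      lrBody, lrHead = lrBody, momentum = 0.9,
                      weightDecay = 0, dropFactor = 1, dropEvery = Inf,
                      seed = 1L, Xval = NULL, yval = NULL,
                      selectBest = FALSE, clipNorm = 5,
                      valGroups = NULL) {
  loss <- match.arg(loss)
  n <- nrow(X)
  batchSize <- min(batchSize, n)
  set.seed(seed)
  history <- numeric(epochs)
  valAcc <- if (!is.null(Xval)) numeric(epochs) else NULL
  best <- list(acc = -Inf, layers = NULL, epoch = 0L)
  fb <- lrBody; fh <- lrHead
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / batchSize)
    epLoss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * batchSize + 1L):min(b * batchSize, n)]
      fwd <- .nnForward(net, X[idx, , drop = FALSE], keep = TRUE)
      lg <- if (loss == "ce") .ceLossGrad(fwd$out, y[idx])
            else .mseLossGrad(fwd$out, y[idx, , drop = FALSE])
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite training loss at epoch %d", ep))
      bk <- .nnBackward(net, fwd, lg$grad)
      net <- .sgdStep(net, .clipGrads(bk$grads, clipNorm), fb, fh,
                      momentum, weightDecay)
      epLoss <- epLoss + lg$loss * length(idx)
    }
    history[ep] <- if (loss == "mse") {
      .mseLossGrad(.nnForward(net, X)$out, y)$loss
    } else epLoss / n
    if (!is.finite(history[ep]))
      stop(sprintf("non-finite training loss at epoch %d", ep))
    if (!is.null(Xval)) {
      pv <- .nnForward(net, Xval)$out
      if (!is.null(valGroups)) {
        # validation accuracy after composing label groups (e.g. sub-class
        # probability mass summed per parent class)
        P <- .softmax(pv)
        G <- max(valGroups) + 1L
        Pg <- vapply(seq_len(G) - 1L, function(g)
          rowSums(P[, valGroups == g, drop = FALSE]), numeric(nrow(P)))
        valAcc[ep] <- mean(max.col(Pg, ties.method = "first") - 1L == yval)
      } else
        valAcc[ep] <- mean(max.col(pv, ties.method = "first") - 1L == yval)
      if (selectBest && valAcc[ep] > best$acc) {
        best <- list(acc = valAcc[ep], layers = net$layers, epoch = ep)
      }
    }
    if (is.finite(dropEvery) && ep %% dropEvery == 0L) {
      fb <- fb * dropFactor; fh <- fh * dropFactor
    }
  }
  if (selectBest && !is.null(best$layers)) net$layers <- best$layers
  list(net = net, history = history, valAcc = valAcc,
       bestEpoch = if (selectBest) best$epoch else epochs)
}
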