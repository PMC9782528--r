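# Independent reference implementations used as oracles. These are written
# directly from the defining equations as plain loops and stay independent
# of the package's vectorised code paths.

# cross-correlation with "same" zero padding, one image
convOracle <- function(img, Warr, b) {
  H <- dim(img)[1L]; W <- dim(img)[2L]; Cin <- dim(img)[3L]
  k <- dim(Warr)[1L]; Cout <- dim(Warr)[4L]
  p <- (k - 1L) %/% 2L
  P <- array(0, c(H + 2L * p, W + 2L * p, Cin))
  P[p + seq_len(H), p + seq_len(W), ] <- img
  O <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- b[co]
    for (u in seq_len(k)) for (v in seq_len(k)) for (ci in seq_len(Cin))
      s <- s + P[i + u - 1L, j + v - 1L, ci] * Warr[u, v, ci, co]
    O[i, j, co] <- s
  }
  O
}

# brute-force density-reachability closure. Returns the exact partition of
# core points (grown by transitive closure over directly-density-reachable
# cores) plus, for every border point, the set of clusters whose cores can
# claim it; noise is everything else.
dbscanOracle <- function(X, eps, minPts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nbrs) >= minPts
  comp <- rep(NA_integer_, n)
  cl <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    comp[i] <- cl
    repeat {
      grew <- FALSE
      members <- which(core & !is.na(comp) & comp == cl)
      for (j in members) for (m in intersect(nbrs[[j]], which(core)))
        if (is.na(comp[m])) { comp[m] <- cl; grew <- TRUE }
      if (!grew) break
    }
    cl <- cl + 1L
  }
  admissible <- vector("list", n)
  for (i in seq_len(n)) {
    if (core[i]) { admissible[[i]] <- comp[i]; next }
    claims <- sort(unique(comp[intersect(nbrs[[i]],
                                         which(core))]))
    admissible[[i]] <- if (length(claims)) claims else -1L
  }
  list(core = core, coreLabels = comp, admissible = admissible,
       nClusters = cl)
}

# checks a ClusterResult against the closure oracle: core partitions must
# agree exactly (up to relabelling), border points must carry a label some
# adjacent core cluster claims, noise must match
dbscanMatchesOracle <- function(res, orc) {
  lab <- clusterLabels(res)
  core <- orc$core
  if (any(core)) {
    # bijection between package cluster ids and oracle component ids
    tab <- table(lab[core], orc$coreLabels[core])
    if (any(rowSums(tab > 0) != 1L) || any(colSums(tab > 0) != 1L))
      return(FALSE)
    remap <- apply(tab, 1L, function(r) as.integer(colnames(tab)[r > 0]))
    names(remap) <- rownames(tab)
  } else remap <- integer(0)
  for (i in seq_along(lab)) {
    if (core[i]) next
    want <- orc$admissible[[i]]
    got <- if (lab[i] == -1L) -1L else remap[[as.character(lab[i])]]
    if (identical(want, -1L)) {
      if (got != -1L) return(FALSE)
    } else if (!(got %in% want)) return(FALSE)
  }
  TRUE
}

# literal-loop affinity propagation per the responsibility / availability
# updates with damping; same preference rule is passed in by the caller
apOracle <- function(S, preference, damping, maxIter, convIter) {
  n <- nrow(S)
  diag(S) <- preference
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  prevEx <- integer(0); stable <- 0L; it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Rn <- matrix(0, n, n)
    for (i in seq_len(n)) for (k in seq_len(n)) {
      comp <- -Inf
      for (kp in seq_len(n)) if (kp != k)
        comp <- max(comp, A[i, kp] + S[i, kp])
      Rn[i, k] <- S[i, k] - comp
    }
    R <- damping * R + (1 - damping) * Rn
    An <- matrix(0, n, n)
    for (i in seq_len(n)) for (k in seq_len(n)) {
      if (i == k) {
        s <- 0
        for (ip in seq_len(n)) if (ip != k) s <- s + max(0, R[ip, k])
        An[k, k] <- s
      } else {
        s <- R[k, k]
        for (ip in seq_len(n)) if (ip != i && ip != k)
          s <- s + max(0, R[ip, k])
        An[i, k] <- min(0, s)
      }
    }
    A <- damping * A + (1 - damping) * An
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, prevEx) && length(ex)) {
      stable <- stable + 1L
      if (stable >= convIter) break
    } else stable <- 0L
    prevEx <- ex
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (!length(ex)) ex <- which.max(diag(R) + diag(A))
  lab <- apply(S[, ex, drop = FALSE], 1L, which.max)
  lab[ex] <- seq_along(ex)
  list(ex = as.integer(ex), labels = as.integer(lab - 1L))
}

lowPreference <- function(S) {
  off <- S[row(S) != col(S)]
  2 * min(off) - max(off)
}

# gaussian blob instances for clustering tests; centres are redrawn until
# pairwise separation is at least `sep` so planted membership is unambiguous
blobInstance <- function(n, kBlobs, d = 2, sep = 6, sd = 0.5) {
  repeat {
    ctrs <- matrix(stats::rnorm(kBlobs * d, sd = sep), kBlobs, d)
    if (kBlobs == 1L || min(stats::dist(ctrs)) >= sep) break
  }
  assign <- sample.int(kBlobs, n, replace = TRUE)
  list(X = ctrs[assign, , drop = FALSE] +
         matrix(stats::rnorm(n * d, sd = sd), n, d),
       truth = assign - 1L)
}

flattenSet <- function(set) {
  d <- dim(images(set))
  t(matrix(images(set), prod(d[1:3]), d[4L]))
}

# a quickly trained two-class model on the patch fixture, reused across
# Grad-CAM tests
trainedPatchModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set <- generatePatchSet(nPerClass = 40L, seed = 1L)
      cache <<- list(
        set = set,
        model = trainClassifier(set, "small_cnn",
          tuneConfig(mode = "deep", epochs = 15L, lrBody = 0.01,
                     lrHead = 0.01, batchSize = 32L, weightDecay = 1e-4,
                     seed = 1L)))
    }
    cache
  }
})

# hand-built linear-in-activations model: conv1 passes the input through
# unchanged (delta kernel), head weights chosen per class so the class
# score is an exact linear functional of the activation map
deltaKernel <- function(cin = 1L, cout = 1L) {
  W <- array(0, c(3, 3, cin, cout))
  for (c in seq_len(min(cin, cout))) W[2, 2, c, c] <- 1
  W
}

linearToyModel <- function(side = 4L, headW) {
  ns <- asNamespace("ClassDecomp")
  layers <- list(
    ns$.convLayer("conv1", 3L, 1L, 1L, Warr = deltaKernel(), b = 0),
    ns$.reluLayer("relu1"),
    ns$.flattenLayer("flatten"),
    ns$.denseLayer("logits", side * side, ncol(headW), W = headW,
                   b = numeric(ncol(headW))))
  net <- ns$.makeNet(layers, c(side, side, 1L))
  structure(list(net = net,
                 classNames = sprintf("c%d", seq_len(ncol(headW)) - 1L),
                 inputShape = c(side, side, 1L),
                 config = tuneConfig()),
            class = "CNNClassifier")
}
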