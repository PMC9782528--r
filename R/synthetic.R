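# Synthetic image generator.
#
# Every class is a mixture of planted sub-clusters; every sub-cluster is a
# parametric texture motif (an oriented sinusoidal grating plus a field of
# Gaussian blobs at fixed per-motif positions). Motifs are chosen so that
# sub-clusters differ in orientation, spatial frequency and blob count --
# second-order statistics a small CNN or CAE can learn -- mimicking
# histology-style texture classes without real data. Between-class overlap
# is a convex blend of each class's motif parameters toward one shared
# motif bank, giving a continuous dial from disjoint appearance (0) to a
# single shared bank (1). Intensities are quantised to the 8-bit grid so
# that PNG round trips are bit-exact.

#' Specification of a synthetic labelled dataset
#'
#' @param nClasses number of classes.
#' @param subclustersPerClass integer vector, planted sub-cluster count per
#'   class.
#' @param samplesPerSubcluster list (one entry per class) of integer
#'   vectors of per-sub-cluster sample counts; class sizes are their sums,
#'   so imbalance is declared directly. Default: the 600-image standard
#'   fixture with class sizes 240/120/240.
#' @param imageSide image side in pixels (>= 8).
#' @param overlap real in [0, 1]; 0 gives disjoint per-class motif banks, 1
#'   draws every class from one shared bank.
#' @param noiseSd standard deviation of additive Gaussian pixel noise.
#' @param channels 1 (grayscale) or 3 (gray replicated, for backbones that
#'   expect RGB).
#' @param seed integer; identical specs produce bit-identical datasets.
#' @return A list of class \code{"SyntheticSpec"}.
#' @examples
#' spec <- syntheticSpec(nClasses = 2, subclustersPerClass = c(1, 1),
#'                       samplesPerSubcluster = list(5, 5))
#' generateLabeled(spec)
#' @export
syntheticSpec <- function(nClasses = 3L,
                          subclustersPerClass = c(4L, 2L, 3L),
                          samplesPerSubcluster = NULL,
                          imageSide = 16L, overlap = 0, noiseSd = 0.05,
                          channels = 1L, seed = 1L) {
  nClasses <- as.integer(nClasses)
  if (nClasses < 1L) stop("at least one class is required")
  if (imageSide < 8L) stop("imageSide must be at least 8")
  if (length(subclustersPerClass) != nClasses)
    stop("subclustersPerClass must have one entry per class")
  if (any(subclustersPerClass < 1L))
    stop("every class needs at least one sub-cluster")
  if (is.null(samplesPerSubcluster))
    samplesPerSubcluster <- lapply(seq_len(nClasses), function(c)
      rep(c(60L, 60L, 80L)[(c - 1L) %% 3L + 1L], subclustersPerClass[c]))
  if (length(samplesPerSubcluster) != nClasses ||
      any(lengths(samplesPerSubcluster) != subclustersPerClass))
    stop("samplesPerSubcluster must match subclustersPerClass")
  if (any(unlist(samplesPerSubcluster) < 1L))
    stop("every sub-cluster needs at least one sample")
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (!(channels %in% c(1L, 3L))) stop("channels must be 1 or 3")
  structure(list(nClasses = nClasses,
                 subclustersPerClass = as.integer(subclustersPerClass),
                 samplesPerSubcluster = lapply(samplesPerSubcluster,
                                               as.integer),
                 imageSide = as.integer(imageSide), overlap = overlap,
                 noiseSd = noiseSd, channels = as.integer(channels),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.MAXBLOBS <- 6L

# one motif = list(theta, freq, nBlobs, pos [.MAXBLOBS x 2])
.drawMotif <- function(theta, freq, nBlobs) {
  list(theta = theta, freq = freq, nBlobs = as.integer(round(nBlobs)),
       pos = matrix(stats::runif(2L * .MAXBLOBS, 0.15, 0.85), .MAXBLOBS, 2L))
}

.blendMotif <- function(own, common, w) {
  list(theta = (1 - w) * own$theta + w * common$theta,
       freq = (1 - w) * own$freq + w * common$freq,
       nBlobs = as.integer(round((1 - w) * own$nBlobs + w * common$nBlobs)),
       pos = (1 - w) * own$pos + w * common$pos)
}

.renderMotif <- function(motif, side, jitter) {
  g <- (seq_len(side) - 1) / side
  xx <- matrix(g, side, side)
  yy <- t(xx)
  th <- motif$theta + jitter$theta
  img <- 0.5 + (0.35 + jitter$amp) *
    sin(2 * pi * motif$freq * (xx * cos(th) + yy * sin(th)) + jitter$phase)
  if (motif$nBlobs > 0L) {
    s2 <- 2 * 0.08^2
    for (b in seq_len(motif$nBlobs)) {
      cx <- motif$pos[b, 1L] + jitter$pos[b, 1L]
      cy <- motif$pos[b, 2L] + jitter$pos[b, 2L]
      img <- img + 0.3 * exp(-((xx - cx)^2 + (yy - cy)^2) / s2)
    }
  }
  img
}

# Per-image structural variability (grating phase and orientation, blob
# placement), scaled by the noise level so that noiseSd = 0 renders each
# motif deterministically and the planted sub-clusters stay recoverable by
# nearest centroid. At the default noiseSd = 0.05 the phase wanders over a
# substantial part of the cycle and the orientation wobbles a few degrees:
# sub-clusters are texture populations, not template stacks.
.drawJitter <- function(noiseSd) {
  sc <- min(1, noiseSd / 0.05)
  list(phase = stats::runif(1, -1.2, 1.2) * sc,
       theta = stats::rnorm(1, 0, 0.05) * sc,
       amp = 0,
       pos = matrix(stats::rnorm(2L * .MAXBLOBS, 0, 0.03), .MAXBLOBS, 2L) *
         sc)
}

.quantise <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255

# deterministic, well-spread parameter banks: orientations equispaced in
# [0, pi), frequencies and blob counts cycling over small banks. Grating
# frequencies are whole cycles per image so the texture tiles the patch
# and pooled statistics are insensitive to the per-image phase.
.motifBanks <- function(spec) {
  J <- spec$subclustersPerClass
  total <- sum(J)
  freqBank <- c(2, 3, 4, 6)
  blobBank <- c(0L, 2L, 4L)
  own <- vector("list", spec$nClasses)
  g <- 0L
  for (c in seq_len(spec$nClasses)) {
    own[[c]] <- vector("list", J[c])
    for (j in seq_len(J[c])) {
      g <- g + 1L
      own[[c]][[j]] <- .drawMotif(pi * (g - 0.5) / total,
                                  freqBank[(g - 1L) %% 4L + 1L],
                                  blobBank[(g - 1L) %% 3L + 1L])
    }
  }
  maxJ <- max(J)
  common <- lapply(seq_len(maxJ), function(j)
    .drawMotif(pi * (j - 0.5) / maxJ, freqBank[j %% 4L + 1L],
               blobBank[j %% 3L + 1L]))
  list(own = own, common = common)
}

.renderSet <- function(motifs, counts, side, noiseSd) {
  n <- sum(counts)
  imgs <- array(0, c(side, side, 1L, n))
  i <- 0L
  for (m in seq_along(motifs)) {
    for (r in seq_len(counts[m])) {
      i <- i + 1L
      img <- .renderMotif(motifs[[m]], side, .drawJitter(noiseSd))
      if (noiseSd > 0)
        img <- img + stats::rnorm(side * side, 0, noiseSd)
      imgs[, , 1L, i] <- .quantise(img)
    }
  }
  imgs
}

#' Generate a labelled synthetic image set
#'
#' Renders every class as its declared planted sub-clusters (ground-truth
#' sub-labels are recorded), assigns a 60/20/20 train/val/test split
#' stratified per class, and is bit-reproducible given the spec seed. At
#' \code{noiseSd = 0} the sub-clusters are separated well enough that a
#' nearest-centroid classifier on raw pixels recovers them exactly.
#'
#' @param spec a [syntheticSpec()] object.
#' @return A [LabeledImageSet-class] with \code{subLabels} set; the motif
#'   parameters used are kept in \code{metadata$motifs}.
#' @export
generateLabeled <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  banks <- .motifBanks(spec)
  motifs <- list(); labels <- integer(0); subs <- integer(0)
  counts <- integer(0)
  g <- 0L
  for (c in seq_len(spec$nClasses)) {
    for (j in seq_len(spec$subclustersPerClass[c])) {
      g <- g + 1L
      motifs[[g]] <- .blendMotif(banks$own[[c]][[j]], banks$common[[j]],
                                 spec$overlap)
      nij <- spec$samplesPerSubcluster[[c]][j]
      counts <- c(counts, nij)
      labels <- c(labels, rep(c - 1L, nij))
      subs <- c(subs, rep(g - 1L, nij))
    }
  }
  imgs <- .renderSet(motifs, counts, spec$imageSide, spec$noiseSd)
  if (spec$channels == 3L)
    imgs <- imgs[, , rep(1L, 3L), , drop = FALSE]
  set <- LabeledImageSet(imgs, labels,
                         classNames = sprintf("class_%d",
                                              seq_len(spec$nClasses) - 1L),
                         subLabels = subs,
                         metadata = list(motifs = motifs, spec = spec))
  assignSplits(set, seed = spec$seed)
}

#' Assign stratified train/val/test splits
#'
#' @param set a [LabeledImageSet-class].
#' @param fractions train/val/test proportions summing to 1 (default the
#'   conventional 60/20/20).
#' @param seed integer seed for the within-class shuffle.
#' @return The set with its \code{split} slot filled.
#' @export
assignSplits <- function(set, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  n <- nImages(set)
  split <- character(n)
  for (c in unique(imageLabels(set))) {
    idx <- which(imageLabels(set) == c)
    idx <- idx[sample.int(length(idx))]
    nTrain <- round(length(idx) * fractions[1L])
    nVal <- round(length(idx) * fractions[2L])
    split[idx[seq_len(nTrain)]] <- "train"
    split[idx[nTrain + seq_len(nVal)]] <- "val"
    rest <- idx[-seq_len(nTrain + nVal)]
    split[rest] <- "test"
  }
  initialize(set, split = split)
}

#' Generate a related unlabelled image pool
#'
#' Draws images from \code{nModes} appearance modes built from the same
#' motif families as the labelled banks but at offset orientations and
#' non-bank frequencies: related to, but not identical with, any labelled
#' sub-cluster. The generating mode index is stored in the labels slot
#' purely as a test oracle.
#'
#' @param spec a [syntheticSpec()] (supplies image size, noise and seed).
#' @param nImages number of pool images (>= nModes).
#' @param nModes number of appearance modes.
#' @return A [LabeledImageSet-class] whose labels are mode indices.
#' @export
generateUnlabeled <- function(spec, nImages, nModes = 3L) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  nModes <- as.integer(nModes)
  if (nModes < 1L) stop("nModes must be at least 1")
  if (nImages < nModes) stop("nImages must be at least nModes")
  set.seed(spec$seed + 99991L)
  modes <- lapply(seq_len(nModes), function(m)
    .drawMotif(pi * (m - 0.5) / nModes + pi / (4 * nModes),
               2.6 + 1.3 * m, (m %% 3L) * 2L))
  counts <- diff(round(seq(0, nImages, length.out = nModes + 1L)))
  imgs <- .renderSet(modes, counts, spec$imageSide, spec$noiseSd)
  if (spec$channels == 3L)
    imgs <- imgs[, , rep(1L, 3L), , drop = FALSE]
  labels <- rep(seq_len(nModes) - 1L, counts)
  LabeledImageSet(imgs, labels,
                  classNames = sprintf("mode_%d", seq_len(nModes) - 1L),
                  subLabels = labels,
                  metadata = list(motifs = modes, spec = spec))
}

#' Generate a two-class set with a planted discriminative patch
#'
#' Both classes share the same grating background; the positive class
#' additionally carries a small high-frequency checkerboard patch at a
#' random location. The patch bounding boxes (row0, col0, row1, col1,
#' 1-based, NA for the background class) are stored in
#' \code{metadata$boxes} as localisation ground truth for attention-map
#' checks.
#'
#' @param nPerClass images per class.
#' @param imageSide image side in pixels.
#' @param patchSide side of the planted patch.
#' @param noiseSd Gaussian pixel noise level.
#' @param seed integer seed.
#' @return A [LabeledImageSet-class] with classes \code{background} and
#'   \code{patched}.
#' @export
generatePatchSet <- function(nPerClass = 40L, imageSide = 16L,
                             patchSide = 5L, noiseSd = 0.05, seed = 1L) {
  stopifnot(imageSide >= 8L, patchSide >= 2L, patchSide < imageSide)
  set.seed(seed)
  n <- 2L * nPerClass
  imgs <- array(0, c(imageSide, imageSide, 1L, n))
  boxes <- matrix(NA_integer_, n, 4L,
                  dimnames = list(NULL, c("row0", "col0", "row1", "col1")))
  bg <- .drawMotif(pi / 6, 2, 0L)
  checker <- outer(seq_len(patchSide), seq_len(patchSide),
                   function(i, j) ifelse((i + j) %% 2L == 0L, 0.95, 0.05))
  labels <- rep(c(0L, 1L), each = nPerClass)
  for (i in seq_len(n)) {
    img <- .renderMotif(bg, imageSide, .drawJitter(noiseSd))
    if (labels[i] == 1L) {
      r0 <- sample.int(imageSide - patchSide + 1L, 1L)
      c0 <- sample.int(imageSide - patchSide + 1L, 1L)
      img[r0:(r0 + patchSide - 1L), c0:(c0 + patchSide - 1L)] <- checker
      boxes[i, ] <- c(r0, c0, r0 + patchSide - 1L, c0 + patchSide - 1L)
    }
    if (noiseSd > 0) img <- img + stats::rnorm(imageSide^2, 0, noiseSd)
    imgs[, , 1L, i] <- .quantise(img)
  }
  set <- LabeledImageSet(imgs, labels,
                         classNames = c("background", "patched"),
                         metadata = list(boxes = boxes))
  assignSplits(set, seed = seed)
}

#' Standard study fixtures
#'
#' \code{standardFixture()} is the 600-image, 3-class set with planted
#' sub-cluster counts (4, 2, 3) and no class overlap used throughout the
#' package's recovery checks. \code{irregularFixture()} is its harder
#' variant with 3:1 class imbalance (180/60/120 images) and overlap 0.5,
#' exhibiting the data irregularities (imbalance, multimodality, boundary
#' overlap) the decomposition method targets.
#'
#' @param seed integer seed.
#' @return A [LabeledImageSet-class].
#' @export
standardFixture <- function(seed = 1L) {
  generateLabeled(syntheticSpec(seed = seed))
}

#' @rdname standardFixture
#' @export
irregularFixture <- function(seed = 1L) {
  generateLabeled(syntheticSpec(
    samplesPerSubcluster = list(c(45L, 45L, 45L, 45L), c(30L, 30L),
                                c(40L, 40L, 40L)),
    overlap = 0.5, seed = seed))
}
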