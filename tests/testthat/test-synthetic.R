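test_that("generator honours declared class and sub-cluster structure", {
  spec <- syntheticSpec(nClasses = 2L, subclustersPerClass = c(1L, 1L),
                        samplesPerSubcluster = list(5L, 5L), seed = 4L)
  set <- generateLabeled(spec)
  expect_equal(nImages(set), 10L)
  expect_equal(imageLabels(set), rep(0:1, each = 5L))
  expect_equal(subLabels(set), imageLabels(set))

  spec3 <- syntheticSpec(seed = 7L)
  set3 <- generateLabeled(spec3)
  expect_equal(length(unique(subLabels(set3))), 9L)
  expect_equal(as.integer(table(imageLabels(set3))), c(240L, 120L, 240L))
})

test_that("identical specs produce bit-identical datasets", {
  spec <- syntheticSpec(seed = 11L)
  a <- generateLabeled(spec)
  b <- generateLabeled(spec)
  expect_identical(images(a), images(b))
  expect_identical(splitTags(a), splitTags(b))
  p1 <- generateUnlabeled(spec, nImages = 30, nModes = 3)
  p2 <- generateUnlabeled(spec, nImages = 30, nModes = 3)
  expect_identical(images(p1), images(p2))
})

test_that("planted sub-clusters are exactly recoverable at zero noise", {
  set <- generateLabeled(syntheticSpec(noiseSd = 0, seed = 3L))
  X <- flattenSet(set)
  sub <- subLabels(set)
  centroids <- vapply(sort(unique(sub)), function(s)
    colMeans(X[sub == s, , drop = FALSE]), numeric(ncol(X)))
  pred <- apply(X, 1L, function(r)
    which.min(colSums((centroids - r)^2)) - 1L)
  expect_equal(mean(pred == sub), 1.0)
})

test_that("splits are 60/20/20 stratified per class", {
  set <- standardFixture(2L)
  for (k in 0:2) {
    s <- splitTags(set)[imageLabels(set) == k]
    expect_equal(as.integer(table(factor(s, c("train", "val", "test")))),
                 as.integer(round(length(s) * c(0.6, 0.2, 0.2))))
  }
})

test_that("overlap = 1 draws all classes from one motif bank", {
  spec <- syntheticSpec(nClasses = 2L, subclustersPerClass = c(2L, 2L),
                        samplesPerSubcluster = list(c(3L, 3L), c(3L, 3L)),
                        overlap = 1, seed = 5L)
  set <- generateLabeled(spec)
  m <- set@metadata$motifs
  # motifs 1,2 belong to class 1, motifs 3,4 to class 2; at full overlap
  # the j-th motif of every class collapses onto the shared bank
  expect_equal(m[[1L]]$theta, m[[3L]]$theta)
  expect_equal(m[[2L]]$freq, m[[4L]]$freq)
  expect_equal(m[[1L]]$pos, m[[3L]]$pos)
})

test_that("unlabelled pool carries mode labels and respects mode count", {
  spec <- syntheticSpec(seed = 9L)
  p1 <- generateUnlabeled(spec, nImages = 12, nModes = 1)
  expect_equal(unique(imageLabels(p1)), 0L)
  p3 <- generateUnlabeled(spec, nImages = 30, nModes = 3)
  expect_setequal(unique(imageLabels(p3)), 0:2)
  expect_equal(nImages(p3), 30L)
})

test_that("invalid specs are rejected", {
  expect_error(syntheticSpec(nClasses = 0L), "at least one class")
  expect_error(syntheticSpec(imageSide = 4L), "at least 8")
  expect_error(syntheticSpec(subclustersPerClass = c(1L, 1L)),
               "one entry per class")
  expect_error(syntheticSpec(overlap = 1.5), "overlap")
  expect_error(generateUnlabeled(syntheticSpec(), nImages = 2, nModes = 3),
               "at least nModes")
})

test_that("patch fixture plants boxes only in the positive class", {
  set <- generatePatchSet(nPerClass = 10L, seed = 2L)
  boxes <- set@metadata$boxes
  expect_true(all(is.na(boxes[imageLabels(set) == 0L, 1L])))
  pos <- boxes[imageLabels(set) == 1L, , drop = FALSE]
  expect_true(all(!is.na(pos)))
  expect_true(all(pos[, 3L] - pos[, 1L] == 4L))
  expect_true(all(pos >= 1L & pos <= 16L))
})
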