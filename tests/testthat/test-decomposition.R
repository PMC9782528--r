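test_that("PCA keeps the fewest components reaching the variance target", {
  # rank-1 data embedded in 5-D
  v <- rnorm(5)
  X <- outer(seq(-2, 2, length.out = 10), v)
  expect_equal(pcaReduce(X, 0.5)$nComponents, 1L)
  expect_equal(pcaReduce(X, 1.0)$nComponents, 1L)

  # sample covariance exactly diag(9, 1) scaled: 9/10 meets threshold 0.9
  X2 <- cbind(c(-3, -3, 3, 3), c(-1, 1, -1, 1))
  red <- pcaReduce(X2, 0.9)
  expect_equal(red$nComponents, 1L)
  expect_equal(red$explained, c(0.9, 0.1))

  # full-rank data at threshold 1 keeps all d components
  set.seed(1)
  Xf <- matrix(rnorm(60), 20, 3)
  full <- pcaReduce(Xf, 1.0)
  expect_equal(full$nComponents, 3L)
  expect_true(all(diff(full$explained) <= 1e-12))
  expect_lt(max(abs(crossprod(full$rotation) - diag(3))), 1e-8)

  expect_warning(z <- pcaReduce(matrix(1, 6, 3), 0.9), "zero-variance")
  expect_equal(z$nComponents, 1L)
})

test_that("cosine similarity matches its defining formula", {
  X <- rbind(c(1, 2, 3), c(1, 2, 3), c(4, 5, 6), c(-2, 1, 0))
  S <- cosineSimilarity(X)
  expect_equal(S[1L, 2L], 1.0)
  expect_equal(S[1L, 3L], 32 / (sqrt(14) * sqrt(77)), tolerance = 1e-6)
  expect_equal(S[1L, 4L], 0)          # orthogonal
  expect_true(isSymmetric(unname(S)))
  expect_error(cosineSimilarity(rbind(c(1, 1), c(0, 0))), "row")
})

test_that("affinity propagation handles degenerate inputs", {
  one <- affinityPropagation(matrix(0, 1, 1))
  expect_equal(nClusters(one), 1L)
  expect_equal(exemplars(one), 1L)
  expect_warning(flat <- affinityPropagation(matrix(1, 4, 4)),
                 "similarities equal")
  expect_equal(nClusters(flat), 1L)
  expect_error(affinityPropagation(matrix(0, 3, 3), damping = 0.3))
})

test_that("affinity propagation reproduces the message-passing oracle", {
  set.seed(21)
  for (trial in 1:6) {
    inst <- blobInstance(sample(20:50, 1), sample(2:3, 1), sep = 6,
                         sd = 0.5)
    S <- negSqEuclidean(inst$X)
    # median preference: the classical choice for negative squared
    # Euclidean similarities
    res <- affinityPropagation(S, preference = "median", damping = 0.9,
                               maxIter = 300L, convIter = 20L)
    orc <- apOracle(unname(as.matrix(S)),
                    median(S[row(S) != col(S)]), 0.9, 300L, 20L)
    expect_identical(exemplars(res), orc$ex)
    expect_identical(clusterLabels(res), orc$labels)
  }
  # two far-separated tight pairs -> two clusters
  pairs <- rbind(c(0, 0), c(0, 0.1), c(9, 9), c(9, 9.1))
  r <- affinityPropagation(negSqEuclidean(pairs))
  expect_equal(nClusters(r), 2L)
  expect_true(hasConverged(r))
})

test_that("three planted blobs are recovered exactly (n = 60)", {
  set.seed(2)
  ctrs <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  X <- ctrs[rep(1:3, each = 20L), ] +
    matrix(rnorm(120, sd = 0.5), 60, 2)
  S <- negSqEuclidean(X)
  res <- affinityPropagation(S, preference = "median")
  orc <- apOracle(unname(as.matrix(S)), median(S[row(S) != col(S)]),
                  0.9, 1000L, 50L)
  expect_equal(nClusters(res), 3L)
  expect_identical(clusterLabels(res), orc$labels)
  expect_gte(ariScore(clusterLabels(res), rep(0:2, each = 20L)), 0.95)
})

test_that("AP at damping 0.9 converges within the iteration budget", {
  set.seed(5)
  inst <- blobInstance(60, 3, sep = 6, sd = 0.5)
  res <- affinityPropagation(cosineSimilarity(inst$X), damping = 0.9,
                             maxIter = 1000L, convIter = 50L)
  expect_true(hasConverged(res))
  expect_lte(res@iterations, 1000L)
})

test_that("k-means baseline covers the fixed-k contract", {
  set.seed(2)
  inst <- blobInstance(10, 2, sep = 8, sd = 0.3)
  km <- kmeansDecompose(inst$X, k = 2L, seed = 1L)
  expect_equal(ariScore(clusterLabels(km), inst$truth), 1)
  one <- kmeansDecompose(inst$X, k = 1L, seed = 1L)
  expect_equal(nClusters(one), 1L)
  X <- matrix(rnorm(12), 6, 2)
  full <- kmeansDecompose(X, k = 6L, seed = 1L)
  expect_equal(nClusters(full), 6L)
  expect_equal(sort(clusterLabels(full)), 0:5)
  expect_error(kmeansDecompose(X, k = 7L), "at least k")
})

test_that("decomposition conserves samples and recomposes labels", {
  set <- standardFixture(1L)[1:60]
  # identity decomposition: bijection, labels preserved up to renaming
  id <- identityDecomposition(set)
  expect_equal(unname(parentOf(id$map)[subAssignment(id$map)]),
               classNames(set)[imageLabels(set) + 1L])
  expect_equal(nImages(id$dataset), nImages(set))

  # a 6/4 split of one 10-sample class
  imgs <- array(runif(8 * 8 * 10), c(8, 8, 1, 10))
  two <- LabeledImageSet(imgs, c(rep(0L, 10L)), classNames = "tum")
  cl <- list(tum = ClassDecomp:::ClusterResult(rep(c(0L, 1L),
                                               c(6L, 4L))))
  dec <- decomposeClasses(two, cl, method = "kmeans")
  sizes <- table(subAssignment(dec$map))
  expect_equal(as.integer(sizes), c(6L, 4L))
  expect_equal(sum(sizes), 10L)

  # noise is rejected, as is a missing class
  expect_error(decomposeClasses(two, list(tum =
    ClassDecomp:::ClusterResult(c(rep(0L, 9L), -1L)))), "noise")
  expect_error(decomposeClasses(two, list()), "tum")
})

test_that("AP decomposition of the fixture recomposes to original labels", {
  set <- standardFixture(4L)
  X <- flattenSet(set)
  perClass <- list()
  for (k in 0:2) {
    idx <- which(imageLabels(set) == k)
    red <- pcaReduce(X[idx, ], 0.95)
    perClass[[classNames(set)[k + 1L]]] <-
      affinityPropagation(cosineSimilarity(red$features))
  }
  dec <- decomposeClasses(set, perClass, method = "ap")
  expect_equal(nImages(dec$dataset), nImages(set))
  recomposed <- unname(parentOf(dec$map)[subAssignment(dec$map)])
  expect_equal(recomposed, classNames(set)[imageLabels(set) + 1L])
  # conservation per class
  for (cn in classNames(set)) {
    kids <- childrenOf(dec$map)[[cn]]
    expect_equal(sum(subAssignment(dec$map) %in% kids),
                 sum(classNames(set)[imageLabels(set) + 1L] == cn))
  }
})

test_that("sub-clusters without training members are merged", {
  imgs <- array(runif(8 * 8 * 12), c(8, 8, 1, 12))
  set <- LabeledImageSet(imgs, rep(0:1, each = 6L),
                         classNames = c("a", "b"),
                         split = rep(c("train", "test"), 6L))
  lab <- c(0L, 0L, 0L, 1L, 1L, 1L)
  # class a: cluster 1's members all land in the test split
  lab[c(4L, 5L, 6L)] <- 1L
  splitA <- splitTags(set)[imageLabels(set) == 0L]
  perClass <- list(a = ClassDecomp:::ClusterResult(
                     ifelse(splitA == "test", 1L, 0L)),
                   b = ClassDecomp:::ClusterResult(rep(0L, 6L)))
  merged <- ClassDecomp:::.mergeUncoveredClusters(set, perClass)
  expect_equal(nClusters(merged$a), 1L)
})
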