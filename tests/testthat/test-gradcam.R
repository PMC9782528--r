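test_that("hand-built linear model reproduces the analytic attention map", {
  A <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)      # activation map
  img <- A + 0.5                                # net sees img - 0.5 = A
  # class 0 score = sum(A) (gradient 1 everywhere); class 1 = -sum(A)
  headW <- cbind(rep(1, 4), rep(-1, 4))
  m <- linearToyModel(side = 2L, headW = headW)
  g <- gradCAM(m, img, targetClass = 0L, layer = "relu1")
  expect_equal(g@weights, 1)
  expect_equal(g@rawMap, A, tolerance = 1e-6)
  expect_equal(dim(g@heatmap), c(2L, 2L))
  expect_equal(max(g@heatmap), 1)
  # negative multiple of every activation: ReLU of a non-positive sum
  expect_warning(g1 <- gradCAM(m, img, targetClass = 1L, layer = "relu1"),
                 "identically zero")
  expect_true(all(g1@rawMap == 0))
  expect_true(all(g1@heatmap == 0))
})

test_that("two-map weighting matches a brute-force computation", {
  side <- 4L
  ns <- asNamespace("ClassDecomp")
  # two maps: identity copy and a spatial shift of the input
  W <- array(0, c(3, 3, 1, 2))
  W[2, 2, 1, 1] <- 1
  W[1, 1, 1, 2] <- 1
  headW <- cbind(c(rep(2, 16), rep(-1, 16)))
  layers <- list(
    ns$.convLayer("conv1", 3L, 1L, 2L, Warr = W, b = c(0, 0)),
    ns$.reluLayer("relu1"),
    ns$.flattenLayer("flatten"),
    ns$.denseLayer("logits", 32L, 2L,
                   W = cbind(headW, -headW), b = c(0, 0)))
  m <- structure(list(net = ns$.makeNet(layers, c(side, side, 1L)),
                      classNames = c("c0", "c1"),
                      inputShape = c(side, side, 1L),
                      config = tuneConfig()),
                 class = "CNNClassifier")
  set.seed(8)
  img <- matrix(runif(16, 0.5, 1), side, side)
  g <- gradCAM(m, img, 0L, layer = "relu1")
  # brute force: gradients are constant 2 and -1 per map
  fwd <- ns$.nnForward(m$net, matrix(as.vector(img), 1) - 0.5)
  acts <- array(fwd$acts[[3L]][1, ], c(side, side, 2L))
  expected <- pmax(2 * acts[, , 1L] + (-1) * acts[, , 2L], 0)
  expect_equal(g@weights, c(2, -1), tolerance = 1e-8)
  expect_equal(g@rawMap, expected, tolerance = 1e-8)
})

test_that("scaling the class score scales phi but not the heatmap", {
  run <- trainedPatchModel()
  img <- run$set[which(imageLabels(run$set) == 1L)[1L]]
  g1 <- gradCAM(run$model, img, 1L)
  m2 <- run$model
  hi <- length(m2$net$layers)
  m2$net$layers[[hi]]$W <- m2$net$layers[[hi]]$W * 3
  m2$net$layers[[hi]]$b <- m2$net$layers[[hi]]$b * 3
  g2 <- gradCAM(m2, img, 1L)
  expect_equal(g2@weights, 3 * g1@weights, tolerance = 1e-8)
  expect_equal(g2@rawMap, 3 * g1@rawMap, tolerance = 1e-8)
  expect_equal(g2@heatmap, g1@heatmap, tolerance = 1e-8)
})

test_that("maps are non-negative, heatmaps match the input grid", {
  run <- trainedPatchModel()
  idx <- which(imageLabels(run$set) == 1L)[1:3]
  for (i in idx) {
    g <- gradCAM(run$model, run$set[i], 1L)
    expect_true(all(g@rawMap >= 0))
    expect_equal(dim(g@heatmap), dim(images(run$set))[1:2])
    expect_true(max(g@heatmap) <= 1 && min(g@heatmap) >= 0)
  }
  expect_error(gradCAM(run$model, run$set[1], 1L, layer = "relu_fc1"),
               "no spatial dimensions")
  expect_error(gradCAM(run$model, run$set[1], 5L), "unknown target class")
})

test_that("attention localises the planted discriminative patch", {
  run <- trainedPatchModel()
  set <- run$set
  te <- which(splitTags(set) == "test" & imageLabels(set) == 1L)
  boxes <- set@metadata$boxes
  hits <- 0L
  for (i in te) {
    g <- suppressWarnings(gradCAM(run$model, set[i], 1L))
    am <- which(g@heatmap == max(g@heatmap), arr.ind = TRUE)[1L, ]
    b <- boxes[i, ]
    hits <- hits + (am[1L] >= b[1L] && am[1L] <= b[3L] &&
                      am[2L] >= b[2L] && am[2L] <= b[4L])
  }
  expect_gte(hits / length(te), 0.5)   # single seed; 5-seed rate elsewhere
})

test_that("composed explanation is the elementwise max over children", {
  A <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  img <- A + 0.5
  # two sub-classes of one parent with disjoint active quadrants
  headW <- cbind(c(1, 0, 0, 0), c(0, 0, 0, 1), rep(-1, 4))
  m <- linearToyModel(side = 2L, headW = headW)
  m$classNames <- c("p_0", "p_1", "q_0")
  map <- new("DecompositionMap",
             parentOf = c(p_0 = "p", p_1 = "p", q_0 = "q"),
             childrenOf = list(p = c("p_0", "p_1"), q = "q_0"),
             assignment = c("p_0", "p_1", "q_0"), method = "ap")
  g <- explainComposed(m, img, "p", map, layer = "relu1")
  expect_equal(length(g@children), 2L)
  expect_equal(g@rawMap, pmax(g@children[[1L]]@rawMap,
                              g@children[[2L]]@rawMap))
  # union support: each child activates its own corner
  expect_gt(g@rawMap[1L, 1L], 0)
  expect_gt(g@rawMap[2L, 2L], 0)
  # single-child parent is plain gradCAM on that child (q's weights are
  # all negative, so its rectified map is legitimately all zero)
  gq <- suppressWarnings(explainComposed(m, img, "q", map,
                                         layer = "relu1"))
  expect_equal(gq@rawMap,
               suppressWarnings(gradCAM(m, img, "q_0",
                                        layer = "relu1"))@rawMap)
  expect_error(explainComposed(m, img, "zz", map), "no children")
})

test_that("overlay writes a PNG of the input dimensions", {
  run <- trainedPatchModel()
  img <- run$set[1]
  g <- suppressWarnings(gradCAM(run$model, img, 1L))
  out <- file.path(withr::local_tempdir(), "x", "overlay.png")
  overlayHeatmap(img, g, out)
  expect_true(file.exists(out))
  px <- png::readPNG(out)
  expect_equal(dim(px)[1:2], dim(images(run$set))[1:2])
  # zero heatmap: blend reduces to 0.6*image + 0.4*colormap floor
  g0 <- g
  g0@heatmap <- g@heatmap * 0
  out0 <- file.path(withr::local_tempdir(), "zero.png")
  overlayHeatmap(img, g0, out0)
  px0 <- png::readPNG(out0)
  base <- images(run$set)[, , 1L, 1L]
  # colormap floor has zero red component, so red = 0.6 * image exactly
  expect_lt(max(abs(px0[, , 1L] - 0.6 * base)), 0.01)
})
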