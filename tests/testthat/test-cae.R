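smallCAEConfig <- function(epochs = 5L, seed = 1L)
  caeConfig(nConvBlocks = 1L, filtersPerBlock = 3L, epochs = epochs,
            batchSize = 16L, seed = seed)

test_that("forward convolution matches the nested-loop definition", {
  ns <- asNamespace("ClassDecomp")
  set.seed(42)
  for (trial in 1:3) {
    H <- 8L; Cin <- sample(1:2, 1); Cout <- sample(1:3, 1)
    Warr <- array(rnorm(9 * Cin * Cout), c(3, 3, Cin, Cout))
    b <- rnorm(Cout)
    layer <- ns$.convLayer("c", 3L, Cin, Cout, Warr = Warr, b = b)
    X <- matrix(rnorm(2 * H * H * Cin), 2)
    out <- ns$.forwardLayer(layer, X, c(H, H, Cin))$out
    for (n in 1:2) {
      expected <- convOracle(array(X[n, ], c(H, H, Cin)), Warr, b)
      expect_lt(max(abs(as.vector(expected) - out[n, ])), 1e-5)
    }
  }
})

test_that("reconstruction error definition and trivial cases", {
  ns <- asNamespace("ClassDecomp")
  X <- matrix(runif(5 * 12), 5)
  expect_equal(ns$.mseLossGrad(X, X)$loss, 0)       # zero residual => 0
  R <- matrix(rnorm(5 * 12), 5)
  expect_equal(ns$.mseLossGrad(X + R, X)$loss, sum(R^2) / (2 * 5))
})

test_that("training reduces the loss on trivially learnable input", {
  imgs <- array(0.5, c(8, 8, 1, 24))
  set <- LabeledImageSet(imgs, rep(0L, 24L), classNames = "c0")
  cae <- trainCAE(set, smallCAEConfig(epochs = 4L))
  expect_lte(tail(cae$lossHistory, 1), cae$lossHistory[1L])
  expect_lt(tail(cae$lossHistory, 1), 1e-3)
})

test_that("trained CAE beats the best constant-image predictor", {
  pool <- generateUnlabeled(syntheticSpec(seed = 5L), nImages = 200,
                            nModes = 2)
  cae <- trainCAE(pool, caeConfig(nConvBlocks = 1L, filtersPerBlock = 3L,
                                  epochs = 30L, batchSize = 32L,
                                  seed = 2L))
  X <- flattenSet(pool)
  constMSE <- sum(scale(X, scale = FALSE)^2) / (2 * nrow(X))
  expect_lt(tail(cae$lossHistory, 1), constMSE)
  # soft monotonicity: 5-epoch moving average non-increasing
  ma <- stats::filter(cae$lossHistory, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-6))
})

test_that("encode produces ordered, deterministic latent rows", {
  pool <- generateUnlabeled(syntheticSpec(seed = 6L), nImages = 30,
                            nModes = 2)
  cae <- trainCAE(pool, smallCAEConfig())
  one <- encodeImages(cae, pool[1])
  expect_equal(dim(one), c(1L, prod(cae$latentShape)))
  dup <- pool[c(3L, 3L)]
  Z <- encodeImages(cae, dup)
  expect_identical(Z@values[1L, ], Z@values[2L, ])
  expect_lt(prod(cae$latentShape), prod(cae$inputShape))
})

test_that("reconstruction agrees with the recorded final loss", {
  pool <- generateUnlabeled(syntheticSpec(seed = 8L), nImages = 40,
                            nModes = 2)
  cae <- trainCAE(pool, smallCAEConfig(epochs = 6L))
  rec <- reconstructImages(cae, pool, clip = FALSE)
  expect_identical(dim(rec), dim(images(pool)))
  mse <- sum((rec - images(pool))^2) / (2 * nImages(pool))
  expect_lt(abs(mse - tail(cae$lossHistory, 1)), 1e-4)
  # clipped output stays in [0, 1]; repeated calls identical
  recA <- reconstructImages(cae, pool)
  expect_true(min(recA) >= 0 && max(recA) <= 1)
  expect_identical(recA, reconstructImages(cae, pool))
})

test_that("tied decoder weights mirror the flipped encoder kernels", {
  ns <- asNamespace("ClassDecomp")
  pool <- generateUnlabeled(syntheticSpec(seed = 9L), nImages = 24,
                            nModes = 2)
  cfg <- caeConfig(nConvBlocks = 1L, filtersPerBlock = 3L, epochs = 3L,
                   batchSize = 12L, tiedWeights = TRUE, seed = 3L)
  cae <- trainCAE(pool, cfg)
  enc <- cae$net$layers[[1L]]
  dec <- cae$net$layers[[5L]]
  expect_identical(dec$W,
                   ns$.flipTiedKernel(enc$W, enc$k, enc$cin, enc$cout))
})

test_that("invalid CAE configurations are rejected", {
  pool <- generateUnlabeled(syntheticSpec(seed = 2L), nImages = 10,
                            nModes = 2)
  expect_error(caeConfig(filtersPerBlock = c(8L, 4L, 2L)),
               "nConvBlocks")
  # 2 blocks of 64/32 at 16 px would expand, not compress
  expect_error(trainCAE(pool, caeConfig(epochs = 1L)), "compression")
})
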