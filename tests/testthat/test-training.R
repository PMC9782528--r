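fastTune <- function(mode = "deep", epochs = 10L, seed = 1L, ...)
  tuneConfig(mode = mode, epochs = epochs, lrBody = 0.01, lrHead = 0.01,
             batchSize = 32L, weightDecay = 1e-4, seed = seed, ...)

test_that("tuning modes freeze the declared parameter groups", {
  set <- generatePatchSet(nPerClass = 20L, seed = 1L)
  before <- trainClassifier(set, "small_cnn",
                            tuneConfig(mode = "shallow", epochs = 1L,
                                       batchSize = 16L, seed = 2L))
  after <- trainClassifier(set, before,
                           tuneConfig(mode = "shallow", epochs = 3L,
                                      lrHead = 0.05, batchSize = 16L,
                                      seed = 2L))
  bodyIdx <- c(1L, 4L, 8L)            # conv1, conv2, fc1
  for (i in bodyIdx)
    expect_identical(after$net$layers[[i]]$W, before$net$layers[[i]]$W)
  expect_false(identical(after$net$layers[[10L]]$W,
                         before$net$layers[[10L]]$W))

  deep <- trainClassifier(set, before, fastTune(epochs = 2L, seed = 2L))
  expect_false(identical(deep$net$layers[[1L]]$W,
                         before$net$layers[[1L]]$W))

  fine1 <- trainClassifier(set, before,
                           tuneConfig(mode = "fine", trainableLayers = 1L,
                                      epochs = 2L, lrBody = 0.01,
                                      batchSize = 16L, seed = 2L))
  expect_identical(fine1$net$layers[[1L]]$W, before$net$layers[[1L]]$W)
  expect_identical(fine1$net$layers[[4L]]$W, before$net$layers[[4L]]$W)
  expect_false(identical(fine1$net$layers[[8L]]$W,
                         before$net$layers[[8L]]$W))
})

test_that("a separable two-class problem is learnt to high accuracy", {
  set <- generatePatchSet(nPerClass = 40L, seed = 3L)
  m <- trainClassifier(set, "small_cnn", fastTune(epochs = 15L, seed = 3L))
  tr <- which(splitTags(set) == "train")
  probs <- predictProbs(m, set[tr])
  acc <- evaluateMetrics(probs)@accuracy
  expect_gte(acc, 95)
})

test_that("training is deterministic given the seed", {
  set <- generatePatchSet(nPerClass = 16L, seed = 4L)
  a <- trainClassifier(set, "small_cnn", fastTune(epochs = 4L, seed = 7L))
  b <- trainClassifier(set, "small_cnn", fastTune(epochs = 4L, seed = 7L))
  expect_identical(a$valAcc, b$valAcc)
  expect_identical(a$net$layers[[1L]]$W, b$net$layers[[1L]]$W)
})

test_that("training-split coverage is enforced", {
  imgs <- array(runif(8 * 8 * 8), c(8, 8, 1, 8))
  set <- LabeledImageSet(imgs, rep(0:1, each = 4L),
                         classNames = c("a", "b"),
                         split = c(rep("train", 4L), rep("val", 4L)))
  expect_error(trainClassifier(set, "small_cnn", fastTune(epochs = 1L)),
               "absent from the training split: b")
})

test_that("prediction is a softmax over logits, row-stochastic and stable", {
  ns <- asNamespace("ClassDecomp")
  p <- ns$.softmax(matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(p), c(0.09003057, 0.24472847, 0.66524096),
               tolerance = 1e-6)
  set <- generatePatchSet(nPerClass = 10L, seed = 5L)
  m <- trainClassifier(set, "small_cnn", fastTune(epochs = 2L, seed = 5L))
  dup <- set[c(1L, 1L, 2L)]
  probs <- predictProbs(m, dup)
  expect_equal(rowSums(probs@probs), rep(1, 3L), tolerance = 1e-9)
  expect_identical(probs@probs[1L, ], probs@probs[2L, ])
})

test_that("composition sums child mass and relabels truth", {
  map <- new("DecompositionMap",
             parentOf = c(c0_0 = "c0", c0_1 = "c0", c1_0 = "c1"),
             childrenOf = list(c0 = c("c0_0", "c0_1"), c1 = "c1_0"),
             assignment = c("c0_0", "c0_1", "c1_0"), method = "ap")
  probs <- ProbabilityTable(
    matrix(c(0.4, 0.3, 0.3), 1, 3,
           dimnames = list(NULL, c("c0_0", "c0_1", "c1_0"))), 2L)
  comp <- composeProbs(probs, map)
  expect_equal(as.vector(comp@probs), c(0.7, 0.3))
  expect_equal(comp@truth, 1L)

  # identity decomposition => composition is the identity
  idMap <- new("DecompositionMap", parentOf = c(a_0 = "a", b_0 = "b"),
               childrenOf = list(a = "a_0", b = "b_0"),
               assignment = c("a_0", "b_0"), method = "identity")
  P <- matrix(c(0.2, 0.8, 0.6, 0.4), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("a_0", "b_0")))
  out <- composeProbs(ProbabilityTable(P, c(0L, 1L)), idMap)
  expect_equal(unname(out@probs), unname(P))

  bad <- ProbabilityTable(matrix(1, 1, 1, dimnames = list(NULL, "zz")), 0L)
  expect_error(composeProbs(bad, map), "missing from the map")
})

test_that("composition conserves probability over many random rows", {
  set.seed(31)
  subs <- sprintf("p%d_%d", rep(1:3, c(3, 2, 4)),
                  unlist(lapply(c(3, 2, 4), seq_len)))
  map <- new("DecompositionMap",
             parentOf = stats::setNames(sprintf("p%d", rep(1:3, c(3, 2, 4))),
                                        subs),
             childrenOf = split(subs, rep(sprintf("p%d", 1:3), c(3, 2, 4))),
             assignment = subs, method = "ap")
  raw <- matrix(stats::rexp(1000 * 9), 1000, 9)
  P <- raw / rowSums(raw)
  colnames(P) <- subs
  comp <- composeProbs(ProbabilityTable(P, sample(0:8, 1000, TRUE)), map)
  expect_true(all(abs(rowSums(comp@probs) - 1) < 1e-9))
  # dominance: when every child of one parent beats all other children,
  # that parent is predicted
  P2 <- matrix(0.02, 1, 9, dimnames = list(NULL, subs))
  P2[1, map@childrenOf$p2] <- (1 - 0.02 * 7) / 2
  out <- composeProbs(ProbabilityTable(P2 / sum(P2), 0L), map)
  expect_equal(colnames(out@probs)[which.max(out@probs)], "p2")
})

test_that("metrics match hand-computed confusion quantities", {
  # perfect predictor
  P <- diag(3)[c(1, 2, 3, 1), ]
  colnames(P) <- c("a", "b", "c")
  perfect <- evaluateMetrics(ProbabilityTable(P, c(0L, 1L, 2L, 0L)))
  expect_equal(perfect@accuracy, 100)
  expect_equal(perfect@sensitivity, 100)
  expect_equal(perfect@specificity, 100)
  expect_equal(unname(perfect@perClassAUC), rep(1, 3L))

  # 2-class confusion [[8,2],[1,9]]
  truth <- rep(c(0L, 1L), c(10L, 10L))
  pred <- c(rep(0L, 8L), rep(1L, 2L), rep(0L, 1L), rep(1L, 9L))
  P2 <- cbind(1 - pred, pred) * 0.8 + 0.1
  colnames(P2) <- c("neg", "pos")
  m2 <- evaluateMetrics(ProbabilityTable(P2 / rowSums(P2), truth))
  expect_equal(unname(m2@confusion),
               matrix(c(8L, 1L, 2L, 9L), 2L))
  expect_equal(m2@accuracy, 85)
  # class "neg" one-vs-rest: SN 8/10, SP 9/10
  expect_equal(m2@sensitivity, mean(c(80, 90)))
  expect_equal(m2@specificity, mean(c(90, 80)))

  # probability inversion flips the ranking => AUC 0 per class
  inv <- evaluateMetrics(ProbabilityTable((1 - P) / 2, c(0L, 1L, 2L, 0L)))
  expect_equal(unname(inv@perClassAUC), rep(0, 3L))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  score <- runif(60)
  pos <- rbinom(60, 1, 0.4) == 1
  ours <- ClassDecomp:::.rankAUC(score, pos)
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(pos, score, quiet = TRUE, direction = "<",
              levels = c(FALSE, TRUE)))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("ARI agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(17)
  for (i in 1:5) {
    a <- sample(0:3, 40, TRUE)
    b <- sample(0:2, 40, TRUE)
    expect_equal(ariScore(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("composed accuracy is at least sub-class accuracy through parents", {
  run <- trainedPatchModel()
  set <- run$set
  dec <- identityDecomposition(set)
  te <- which(splitTags(set) == "test")
  probs <- predictProbs(run$model, set[te])
  # identity map: composed metrics equal sub metrics exactly
  colnames(probs@probs) <- paste0(colnames(probs@probs), "_0")
  map <- new("DecompositionMap",
             parentOf = c(background_0 = "background",
                          patched_0 = "patched"),
             childrenOf = list(background = "background_0",
                               patched = "patched_0"),
             assignment = colnames(probs@probs)[probs@truth + 1L],
             method = "identity")
  comp <- composeProbs(probs, map)
  expect_equal(evaluateMetrics(comp)@accuracy,
               evaluateMetrics(probs)@accuracy)
})
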