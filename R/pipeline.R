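# End-to-end orchestration: pseudo-labels -> pretext training ->
# class decomposition -> downstream training -> composition -> metrics,
# with per-stage seeding derived from one master seed, artifact
# persistence and a hash manifest. Re-running a config with the same seed
# reproduces the metrics JSON byte for byte.

.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

.logLine <- function(state, level, fmt, ...) {
  lv <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)
  if (lv[[level]] < lv[[state$logLevel]]) return(invisible())
  msg <- sprintf("[%s] %s", level, sprintf(fmt, ...))
  if (state$console) message(msg)
  if (!is.null(state$file)) cat(msg, "\n", file = state$file, append = TRUE)
  invisible()
}

#' Pipeline configuration
#'
#' Collects every stage's settings in one validated object. Exactly one of
#' \code{labelledRoot} (a class-per-subdirectory image tree read by
#' [readImageSet()]) or \code{synthetic} (arguments for [syntheticSpec()],
#' for self-contained runs) must be given. All stage seeds are derived
#' deterministically from \code{seed}.
#'
#' @param labelledRoot directory of the labelled downstream dataset, or
#'   \code{NULL}.
#' @param unlabelledRoot directory of the unlabelled pool, or \code{NULL}
#'   (required with \code{labelledRoot}).
#' @param synthetic named list of [syntheticSpec()] arguments, or
#'   \code{NULL}.
#' @param pool named list \code{list(nImages =, nModes =)} sizing the
#'   synthetic unlabelled pool.
#' @param outputDir directory that will hold run directories.
#' @param cae named list of [caeConfig()] overrides.
#' @param density list with \code{minPts} (\code{NULL} = the
#'   [defaultMinPts()] heuristic) and \code{eps} (\code{"auto"} = the
#'   [estimateEps()] k-NN heuristic, or a number).
#' @param decomposition list: \code{method} ("ap" or "kmeans"),
#'   \code{damping}, \code{maxIter}, \code{convIter}, \code{pcaThreshold},
#'   \code{k}.
#' @param pretext named list of [tuneConfig()] overrides for the pretext
#'   stage (default mode "deep": coarse transfer learning trains all
#'   layers).
#' @param downstream named list of [tuneConfig()] overrides for the
#'   downstream stage (default mode "fine").
#' @param seed master seed.
#' @param logLevel \code{"DEBUG"}, \code{"INFO"} or \code{"WARN"}.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(labelledRoot = NULL, unlabelledRoot = NULL,
                           synthetic = NULL, pool = list(nImages = 300L,
                                                         nModes = 3L),
                           outputDir = tempfile("classdecomp_runs"),
                           cae = list(), density = list(minPts = NULL,
                                                        eps = "auto"),
                           decomposition = list(), pretext = list(),
                           downstream = list(), seed = 1L,
                           logLevel = "INFO") {
  if (is.null(labelledRoot) == is.null(synthetic))
    stop("exactly one of labelledRoot or synthetic must be given")
  if (!is.null(labelledRoot) && is.null(unlabelledRoot))
    stop("unlabelledRoot is required with labelledRoot")
  dec <- utils::modifyList(list(method = "ap", damping = 0.9,
                                maxIter = 1000L, convIter = 50L,
                                pcaThreshold = 0.95, k = 2L), decomposition)
  den <- utils::modifyList(list(minPts = NULL, eps = "auto"), density)
  structure(list(labelledRoot = labelledRoot,
                 unlabelledRoot = unlabelledRoot, synthetic = synthetic,
                 pool = pool, outputDir = outputDir, cae = cae,
                 density = den, decomposition = dec, pretext = pretext,
                 downstream = downstream, seed = as.integer(seed),
                 logLevel = match.arg(logLevel, c("DEBUG", "INFO", "WARN"))),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipelineConfig()] arguments as top-level keys (blocks
#' \code{synthetic:}, \code{cae:}, \code{density:}, \code{decomposition:},
#' \code{pretext:}, \code{downstream:}).
#'
#' @param path YAML file path.
#' @return A \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

.stageData <- function(cfg, state) {
  if (!is.null(cfg$synthetic)) {
    args <- cfg$synthetic
    args$seed <- .deriveSeed(cfg$seed, "data")
    spec <- do.call(syntheticSpec, args)
    labelled <- generateLabeled(spec)
    poolSpec <- spec
    pool <- generateUnlabeled(poolSpec, nImages = cfg$pool$nImages,
                              nModes = cfg$pool$nModes)
    .logLine(state, "INFO", "synthetic data: %d labelled, %d unlabelled",
             nImages(labelled), nImages(pool))
  } else {
    labelled <- readImageSet(cfg$labelledRoot)
    if (!length(splitTags(labelled)))
      labelled <- assignSplits(labelled, seed = .deriveSeed(cfg$seed,
                                                            "split"))
    pool <- readImageSet(cfg$unlabelledRoot)
    .logLine(state, "INFO", "read %d labelled, %d unlabelled images",
             nImages(labelled), nImages(pool))
  }
  list(labelled = labelled, pool = pool)
}

.tuneFromList <- function(overrides, defaults, seed) {
  args <- utils::modifyList(defaults, overrides)
  if (is.null(overrides$seed)) args$seed <- seed
  do.call(tuneConfig, args)
}

.writeFeatureCSV <- function(features, path) {
  df <- data.frame(sample_id = features@sampleIds,
                   features@values, check.names = FALSE)
  colnames(df)[-1L] <- sprintf("f_%d", seq_len(ncol(features@values)) - 1L)
  utils::write.csv(df, path, row.names = FALSE)
}

.jsonWrite <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

.runStages <- function(cfg, runDir, decompose = TRUE, usePretext = TRUE,
                       explain = FALSE) {
  dir.create(runDir, recursive = TRUE, showWarnings = FALSE)
  state <- list(logLevel = cfg$logLevel, console = TRUE,
                file = file.path(runDir, "pipeline.log"))
  artifacts <- character(0)
  stage <- "config"
  res <- tryCatch({
    cfgOut <- cfg; class(cfgOut) <- NULL
    yaml::write_yaml(cfgOut, file.path(runDir, "config.yaml"))
    artifacts["config"] <- "config.yaml"

    stage <- "data"
    dat <- .stageData(cfg, state)
    labelled <- dat$labelled

    pretextModel <- NULL
    if (usePretext) {
      stage <- "cae"
      caeArgs <- cfg$cae
      if (is.null(caeArgs$seed)) caeArgs$seed <- .deriveSeed(cfg$seed, "cae")
      cae <- trainCAE(dat$pool, do.call(caeConfig, caeArgs))
      feats <- encodeImages(cae, dat$pool)
      .writeFeatureCSV(feats, file.path(runDir, "cae_features.csv"))
      artifacts["cae_features"] <- "cae_features.csv"
      .logLine(state, "INFO", "CAE trained, final MSE %.5g, latent dim %d",
               utils::tail(cae$lossHistory, 1), ncol(feats@values))

      stage <- "pseudo_labels"
      minPts <- cfg$density$minPts
      if (is.null(minPts)) minPts <- defaultMinPts(feats)
      eps <- cfg$density$eps
      if (identical(eps, "auto")) eps <- as.numeric(estimateEps(feats,
                                                                minPts))
      cl <- dbscanCluster(feats, eps = eps, minPts = minPts)
      utils::write.csv(data.frame(sample_id = feats@sampleIds,
                                  label = clusterLabels(cl)),
                       file.path(runDir, "pseudo_labels.csv"),
                       row.names = FALSE)
      artifacts["pseudo_labels"] <- "pseudo_labels.csv"
      .logLine(state, "INFO",
               "DBSCAN (eps %.4g, minPts %d): %d pseudo-classes, %d noise",
               eps, minPts, nClusters(cl), sum(clusterLabels(cl) == -1L))

      stage <- "pretext_training"
      if (nClusters(cl) >= 2L) {
        pretext <- makePretextSet(dat$pool, cl)
        pretext <- assignSplits(pretext, c(0.8, 0.2, 0),
                                seed = .deriveSeed(cfg$seed, "pretext_split"))
        preCfg <- .tuneFromList(cfg$pretext,
                                list(mode = "deep", epochs = 10L,
                                     lrBody = 0.01, lrHead = 0.01,
                                     batchSize = 32L, weightDecay = 1e-4,
                                     dropFactor = 0.9, dropEvery = 10L),
                                .deriveSeed(cfg$seed, "pretext"))
        pretextModel <- trainClassifier(pretext, "small_cnn", preCfg)
        saveRDS(pretextModel, file.path(runDir, "pretext_model.rds"))
        artifacts["pretext_model"] <- "pretext_model.rds"
        .logLine(state, "INFO", "pretext model: best val acc %.3f",
                 max(pretextModel$valAcc))
      } else {
        .logLine(state, "WARN",
                 "only %d pseudo-class(es); skipping pretext training",
                 nClusters(cl))
      }
    }

    stage <- "decomposition"
    if (decompose) {
      featBackbone <- trainClassifier(
        labelled,
        backbone = if (is.null(pretextModel)) "small_cnn" else pretextModel,
        config = .tuneFromList(list(),
                               list(mode = "shallow", epochs = 8L,
                                    batchSize = 32L, weightDecay = 1e-4),
                               .deriveSeed(cfg$seed, "featext")))
      dec <- decomposeDataset(labelled, featBackbone,
                              method = cfg$decomposition$method,
                              pcaThreshold = cfg$decomposition$pcaThreshold,
                              damping = cfg$decomposition$damping,
                              maxIter = cfg$decomposition$maxIter,
                              convIter = cfg$decomposition$convIter,
                              k = cfg$decomposition$k,
                              seed = .deriveSeed(cfg$seed, "kmeans"))
      sizes <- table(subAssignment(dec$map))
      .jsonWrite(list(method = dec$map@method,
                      parentOf = as.list(parentOf(dec$map)),
                      sizes = as.list(as.integer(sizes)) |>
                        stats::setNames(names(sizes)),
                      pcaComponents = as.list(dec$nComponents)),
                 file.path(runDir, "decomposition_map.json"))
      artifacts["decomposition_map"] <- "decomposition_map.json"
      .logLine(state, "INFO", "decomposition [%s]: %d sub-classes (%s)",
               dec$map@method, length(parentOf(dec$map)),
               paste(vapply(childrenOf(dec$map), length, integer(1)),
                     collapse = "/"))
    } else {
      dec <- identityDecomposition(labelled)
      .jsonWrite(list(method = "identity",
                      parentOf = as.list(parentOf(dec$map))),
                 file.path(runDir, "decomposition_map.json"))
      artifacts["decomposition_map"] <- "decomposition_map.json"
    }

    stage <- "downstream_training"
    dsCfg <- .tuneFromList(cfg$downstream,
                           list(mode = "fine", trainableLayers = 2L,
                                epochs = 20L, lrBody = 0.002,
                                lrHead = 0.01, batchSize = 32L,
                                weightDecay = 1e-4),
                           .deriveSeed(cfg$seed, "downstream"))
    model <- trainClassifier(dec$dataset,
                             backbone = if (is.null(pretextModel))
                               "small_cnn" else pretextModel,
                             config = dsCfg, composeWith = dec$map)
    saveRDS(model, file.path(runDir, "downstream_model.rds"))
    artifacts["downstream_model"] <- "downstream_model.rds"

    stage <- "composition_metrics"
    testIdx <- which(splitTags(dec$dataset) == "test")
    subProbs <- predictProbs(model, dec$dataset[testIdx])
    composed <- composeProbs(subProbs, dec$map)
    metrics <- evaluateMetrics(composed)
    subMetrics <- evaluateMetrics(subProbs)
    .jsonWrite(list(composed = metricsAsList(metrics),
                    subclass = metricsAsList(subMetrics),
                    nTest = length(testIdx),
                    decomposition = dec$map@method,
                    seed = cfg$seed),
               file.path(runDir, "metrics.json"))
    artifacts["metrics"] <- "metrics.json"
    .logLine(state, "INFO", "composed test accuracy %.2f%% (sub %.2f%%)",
             metrics@accuracy, subMetrics@accuracy)

    if (explain) {
      stage <- "explanation"
      dir.create(file.path(runDir, "heatmaps"), showWarnings = FALSE)
      cn <- names(childrenOf(dec$map))
      parents <- cn[imageLabels(labelled)[testIdx] + 1L]
      take <- testIdx[!duplicated(parents)]
      for (i in take) {
        pc <- cn[imageLabels(labelled)[i] + 1L]
        g <- explainComposed(model, labelled[i], pc, dec$map)
        overlayHeatmap(labelled[i], g,
                       file.path(runDir, "heatmaps",
                                 sprintf("%s_%d.png", pc, i)))
      }
      artifacts["heatmaps"] <- "heatmaps"
    }

    stage <- "manifest"
    files <- artifacts[artifacts != "heatmaps"]
    hashes <- tools::md5sum(file.path(runDir, files))
    names(hashes) <- names(files)
    .jsonWrite(list(runDir = basename(runDir), seed = cfg$seed,
                    artifacts = as.list(files),
                    md5 = as.list(unname(hashes)) |>
                      stats::setNames(names(hashes))),
               file.path(runDir, "manifest.json"))
    list(runDir = runDir, metrics = metrics, subMetrics = subMetrics,
         map = dec$map, model = model, artifacts = artifacts,
         labelled = labelled)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s (partial artifacts in %s)",
                 stage, conditionMessage(e), runDir), call. = FALSE)
  })
  res
}

#' Run the full pipeline
#'
#' Executes pseudo-labelling, pretext training, class decomposition,
#' downstream training, composition and evaluation from one config,
#' persisting every intermediate artifact (features CSV, pseudo-label CSV,
#' model checkpoints, decomposition map JSON, metrics JSON and an md5
#' manifest) under a run directory.
#'
#' @param config a [pipelineConfig()].
#' @param runDir run directory; default a timestamped directory under the
#'   config's \code{outputDir}.
#' @param explain also write composed Grad-CAM overlays for one test image
#'   per class.
#' @return Invisibly, a list with \code{runDir}, \code{metrics} (composed
#'   [MetricsReport-class]), \code{subMetrics}, \code{map}, \code{model}
#'   and \code{artifacts}.
#' @export
runPipeline <- function(config, runDir = NULL, explain = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(runDir))
    runDir <- file.path(config$outputDir,
                        sprintf("run_%s_seed%d",
                                format(Sys.time(), "%Y%m%d_%H%M%S"),
                                config$seed))
  invisible(.runStages(config, runDir, decompose = TRUE, usePretext = TRUE,
                       explain = explain))
}

#' Run the no-decomposition baseline
#'
#' The comparison arm: identical data, split and downstream training
#' configuration, but the backbone trains from random initialisation (no
#' self-supervised pretext) and the decomposition is the identity map, so
#' sub-class metrics equal class metrics. Output follows the same artifact
#' schema as [runPipeline()].
#'
#' @inheritParams runPipeline
#' @return As [runPipeline()].
#' @export
runBaseline <- function(config, runDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(runDir))
    runDir <- file.path(config$outputDir,
                        sprintf("baseline_%s_seed%d",
                                format(Sys.time(), "%Y%m%d_%H%M%S"),
                                config$seed))
  invisible(.runStages(config, runDir, decompose = FALSE,
                       usePretext = FALSE, explain = FALSE))
}

#' Desk-scale pipeline configuration on the irregular fixture
#'
#' The self-contained configuration used by the package's end-to-end
#' checks: the 360-image irregular fixture (3:1 imbalance, overlap 0.5,
#' planted sub-clusters 4/2/3, 16 px images), a 300-image 3-mode unlabelled
#' pool, a single-block CAE (3 filters, 30 epochs, batch 32) and short
#' pretext (10 epochs) and downstream (20 epochs) trainings of the small
#' CNN.
#'
#' @param seed master seed.
#' @param outputDir run-directory root.
#' @return A [pipelineConfig()].
#' @export
deskPipelineConfig <- function(seed = 1L,
                               outputDir = tempfile("classdecomp_runs")) {
  pipelineConfig(
    synthetic = list(
      samplesPerSubcluster = list(c(45L, 45L, 45L, 45L), c(30L, 30L),
                                  c(40L, 40L, 40L)),
      overlap = 0.5),
    pool = list(nImages = 300L, nModes = 3L),
    cae = list(nConvBlocks = 1L, filtersPerBlock = 3L, epochs = 30L,
               batchSize = 32L),
    pretext = list(epochs = 10L),
    downstream = list(epochs = 20L),
    outputDir = outputDir,
    seed = seed, logLevel = "WARN")
}
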