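#' Default end-to-end pipeline configuration
#'
#' Returns the configuration list consumed by [runPipeline()], documenting
#' every tunable: capture counts and geometry source, wavelet settings,
#' segmentation threshold, augmentation policy, split ratio and training
#' hyperparameters. Any subset can be overridden via `...` or loaded from
#' a YAML file with [readPipelineConfig()].
#'
#' @param ... named overrides of the defaults.
#' @return A named list.
#' @examples
#' names(pipelineConfig())
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    config_version = 1L,
    n_present = 100L, n_absent = 100L,
    species = "chironomid",
    image_side = 1200L, noise_sd = 5,
    wavelet_family = "haar", wavelet_level = 1L,
    quality_threshold = 50, crop_size = 300L,
    augmentation = list(rotation_range = 30, shift_range = 0.1,
                        horizontal_flip = TRUE, zoom_range = 0.2,
                        factor = 4L),
    split_ratio = 0.7, stratified = TRUE, lineage_aware = FALSE,
    batch_size = 32L, epochs = 30L, learning_rate = 1e-3,
    optimizer = "Adam", dense_units = 256L,
    grid = NULL,           # e.g. list(epochs = c(200, 300), lr = c(...))
    accuracy_floor = 1.0,
    write_images = FALSE
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' @rdname pipelineConfig
#' @param path path to a YAML configuration file.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the full detection pipeline
#'
#' Executes generate -> wavelet preprocess -> segment -> augment -> split
#' -> train (or grid-search) -> evaluate -> select end-to-end, streaming
#' captures one at a time so full-resolution scenes never accumulate in
#' memory, and persists every stage's artifacts under `outdir`:
#' `segmentation_log.csv`, `dataset_manifest.csv`, `split.csv`,
#' `history.csv` (per-epoch accuracy/loss), `grid_results.csv` when a
#' grid is run, `eval_report.json`, `confusion.csv`, `verdict.json` and a
#' `run_manifest.json` capturing the configuration and master seed for
#' exact reproduction.
#'
#' @param config configuration list from [pipelineConfig()] (or a path
#'   accepted by [readPipelineConfig()]).
#' @param outdir output directory, created if missing.
#' @param seed master seed; every stage derives its own stream from it.
#' @param verbose print stage progress.
#' @return Invisibly, a list with `outdir`, the [EvalReport-class], the
#'   [SelectionVerdict-class], the trained [CNNModel-class] and the
#'   segmentation log.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile("run-"),
                        seed = 0L, verbose = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "generate/segment"
  n <- config$n_present + config$n_absent

  say("[1/6] generating and segmenting %d captures (side %d)",
      n, config$image_side)
  samples <- list()
  log <- NULL
  for (i in seq_len(n)) {
    present <- i <= config$n_present
    s <- captureSeed(seed, i)
    spec <- drawSceneSpec(config$species, seed = s,
                          imageSide = config$image_side,
                          larvaPresent = present, noiseSd = config$noise_sd)
    cap <- generateCapture(spec, seed = s,
                           captureId = sprintf("%s-%s-%04d", config$species,
                                               if (present) "pos" else "neg",
                                               i))
    res <- segmentCapture(cap, qualityThreshold = config$quality_threshold,
                          band = "GRE", family = config$wavelet_family,
                          level = config$wavelet_level,
                          size = config$crop_size)
    log <- rbind(log, res$logRow)
    if (!is.null(res$sample)) {
      samples[[length(samples) + 1L]] <- res$sample
      if (isTRUE(config$write_images))
        writeSampleImage(res$sample, file.path(outdir, "segmented"))
    }
  }
  write.csv(log, file.path(outdir, "segmentation_log.csv"),
            row.names = FALSE)
  if (length(samples) == 0L)
    stop(sprintf("pipeline halted at stage '%s': no samples survived the quality threshold %.1f (log written to %s)",
                 stage, config$quality_threshold, outdir))
  dataset <- new("LarvaDataset", samples = samples)
  lab <- datasetLabels(dataset)
  if (!any(lab == 1L) || !any(lab == 0L))
    stop(sprintf("pipeline halted at stage '%s': need both classes after segmentation (got %d present / %d absent)",
                 stage, sum(lab == 1L), sum(lab == 0L)))

  say("[2/6] augmenting %d samples x factor %d", length(dataset),
      config$augmentation$factor)
  policy <- augmentationPolicy(
    rotationRange = config$augmentation$rotation_range,
    shiftRange = config$augmentation$shift_range,
    horizontalFlip = config$augmentation$horizontal_flip,
    zoomRange = config$augmentation$zoom_range,
    factor = config$augmentation$factor,
    seed = deriveSeed(seed, 2L))
  dataset <- augmentDataset(dataset, policy)
  write.csv(sampleInfo(dataset), file.path(outdir, "dataset_manifest.csv"),
            row.names = FALSE)

  say("[3/6] splitting %d samples %.0f:%.0f", length(dataset),
      100 * config$split_ratio, 100 * (1 - config$split_ratio))
  idx <- splitIndices(dataset, ratio = config$split_ratio,
                      seed = deriveSeed(seed, 3L),
                      stratified = isTRUE(config$stratified),
                      lineageAware = isTRUE(config$lineage_aware))
  write.csv(data.frame(index = seq_len(length(dataset)),
                       part = ifelse(seq_len(length(dataset)) %in% idx$train,
                                     "train", "test")),
            file.path(outdir, "split.csv"), row.names = FALSE)
  trainSet <- dataset[idx$train]
  testSet <- dataset[idx$test]
  xTrain <- asImageArray(trainSet); yTrain <- datasetLabels(trainSet)
  xTest <- asImageArray(testSet); yTest <- datasetLabels(testSet)

  arch <- cnnArchitecture(inputSide = config$crop_size,
                          denseUnits = config$dense_units)
  baseCfg <- trainingConfig(batchSize = config$batch_size,
                            epochs = config$epochs,
                            learningRate = config$learning_rate,
                            optimizer = config$optimizer,
                            splitRatio = config$split_ratio,
                            seed = deriveSeed(seed, 4L))

  if (!is.null(config$grid)) {
    say("[4/6] grid search: %d combinations",
        length(config$grid$epochs) * length(config$grid$lr))
    gs <- gridSearch(xTrain, yTrain,
                     validation = list(x = xTest, y = yTest),
                     epochsGrid = config$grid$epochs,
                     lrGrid = config$grid$lr,
                     arch = arch, baseConfig = baseCfg)
    write.csv(gs$results, file.path(outdir, "grid_results.csv"),
              row.names = FALSE)
    model <- gs$models
  } else {
    say("[4/6] training: %d epochs, lr %g, %s, batch %d",
        config$epochs, config$learning_rate, config$optimizer,
        config$batch_size)
    model <- trainCNN(xTrain, yTrain, arch = arch, config = baseCfg,
                      validation = list(x = xTest, y = yTest))
  }
  write.csv(modelHistory(model), file.path(outdir, "history.csv"),
            row.names = FALSE)

  say("[5/6] evaluating on %d held-out samples", length(yTest))
  probs <- predict(model, xTest)
  report <- classificationMetrics(probs, yTest, modelId = "cnn",
                                  trainingSeconds = trainingSeconds(model))
  jsonlite::write_json(
    list(modelId = report@modelId, accuracy = report@accuracy,
         precision = report@precision, recall = report@recall,
         f1 = report@f1, rmse = report@rmse,
         trainingSeconds = report@trainingSeconds, nEval = report@nEval),
    file.path(outdir, "eval_report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(report@confusion),
            file.path(outdir, "confusion.csv"), row.names = FALSE)

  say("[6/6] model selection")
  verdict <- selectOptimal(list(report),
                           accuracyFloor = config$accuracy_floor)
  jsonlite::write_json(
    list(selected = verdict@selected, floorMet = verdict@floorMet,
         accuracyFloor = verdict@accuracyFloor, ranking = verdict@ranking),
    file.path(outdir, "verdict.json"), auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(
    list(config = config, seed = seed,
         package_version = as.character(utils::packageVersion("larvaDetect")),
         n_segmented = sum(log$verdict == "accepted"),
         n_total = length(dataset)),
    file.path(outdir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(outdir = outdir, report = report, verdict = verdict,
                 model = model, segmentationLog = log))
}
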