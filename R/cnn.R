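#' Construct a CNNArchitecture
#'
#' Defaults reproduce the canonical 10-layer classifier for 300x300
#' 3-channel inputs: conv blocks with 16, 32 and 64 filters of size 3x3
#' (unpadded, ReLU, each followed by 2x2 max pooling), a 256-unit dense
#' ReLU layer, 50% dropout and one sigmoid output unit.
#'
#' @param inputSide input image side in px.
#' @param channels input channels.
#' @param convFilters integer vector of filters per conv block.
#' @param kernelSize square kernel side.
#' @param denseUnits width of the dense hidden layer (256 or 512 in the
#'   canonical layout).
#' @param dropoutRate dropout probability.
#' @return A [CNNArchitecture-class].
#' @examples
#' computeLayerShapes(cnnArchitecture())
#' @export
cnnArchitecture <- function(inputSide = 300L, channels = 3L,
                            convFilters = c(16L, 32L, 64L),
                            kernelSize = 3L, denseUnits = 256L,
                            dropoutRate = 0.5) {
  new("CNNArchitecture", inputSide = as.integer(inputSide),
      channels = as.integer(channels),
      convFilters = as.integer(convFilters),
      kernelSize = as.integer(kernelSize),
      denseUnits = as.integer(denseUnits), dropoutRate = dropoutRate)
}

#' Analytic layer-shape chain of the classifier
#'
#' Computes every layer's output shape without any learning backend: an
#' unpadded k x k convolution maps side s to s - k + 1 and a 2x2 max pool
#' maps s to floor(s / 2); the flatten length is the final side squared
#' times the final filter count. For the default architecture this chain
#' is 298, 149, 147, 73, 71, 35 with flatten length 78,400, and the layer
#' count is 10.
#'
#' @param arch a [CNNArchitecture-class].
#' @return A data.frame with columns `layer`, `side`, `units` (side^2 x
#'   filters for spatial layers, the unit count for flat layers), one row
#'   per layer.
#' @examples
#' computeLayerShapes(cnnArchitecture())
#' @export
computeLayerShapes <- function(arch) {
  stopifnot(is(arch, "CNNArchitecture"))
  side <- arch@inputSide
  rows <- list()
  for (f in arch@convFilters) {
    side <- side - arch@kernelSize + 1L
    if (side <= 0L) stop("convolution would produce a non-positive side")
    rows[[length(rows) + 1L]] <- data.frame(layer = "conv2d", side = side,
                                            units = as.integer(side^2 * f))
    side <- side %/% 2L
    if (side <= 0L) stop("pooling would produce a non-positive side")
    rows[[length(rows) + 1L]] <- data.frame(layer = "maxpool", side = side,
                                            units = as.integer(side^2 * f))
  }
  flat <- as.integer(side^2 * arch@convFilters[length(arch@convFilters)])
  rows[[length(rows) + 1L]] <- data.frame(layer = "flatten", side = NA_integer_,
                                          units = flat)
  rows[[length(rows) + 1L]] <- data.frame(layer = "dense", side = NA_integer_,
                                          units = arch@denseUnits)
  rows[[length(rows) + 1L]] <- data.frame(layer = "dropout", side = NA_integer_,
                                          units = arch@denseUnits)
  rows[[length(rows) + 1L]] <- data.frame(layer = "dense", side = NA_integer_,
                                          units = 1L)
  do.call(rbind, rows)
}

#' @rdname computeLayerShapes
#' @return `flattenLength`: the flatten layer's length.
#' @export
flattenLength <- function(arch) {
  sh <- computeLayerShapes(arch)
  sh$units[sh$layer == "flatten"]
}

#' @rdname computeLayerShapes
#' @return `layerCount`: the number of layers (conv/pool/flatten/dense/
#'   dropout/dense rows); 10 for the default architecture.
#' @export
layerCount <- function(arch) {
  nrow(computeLayerShapes(arch))
}

# Standard 101-layer residual backbone layer graph (v1, ImageNet layout):
# stem 7x7/2 conv (pad 3) and 3x3/2 max pool (pad 1), then four bottleneck
# stages of 3/4/23/3 blocks whose first block downsamples by stride 2 from
# stage 2 on; 2048 output channels. Weighted layers: 1 + 3*(3+4+23+3) = 100
# conv plus the classifier head = 101.
.RESNET101_STAGES <- c(3L, 4L, 23L, 3L)

#' Shape walk through a 101-layer residual backbone
#'
#' Propagates an `inputSide` px square input through the standard
#' residual-network spatial reductions (overall stride 32) using the usual
#' padded-convolution arithmetic `floor((s + 2p - k) / s) + 1`, without
#' instantiating any weights. For a 300 px input the side chain is
#' 300 -> 150 -> 75 -> 38 -> 19 -> 10 and the flattened feature length is
#' 10 x 10 x 2048 = 204,800.
#'
#' @param inputSide input side in px, >= 32 (smaller inputs collapse
#'   before the five stride-2 stages complete).
#' @return `resnetHeadShapes`: a data.frame with columns `stage`, `side`,
#'   `channels`.
#' @examples
#' resnetHeadFlattenSize(300)  # 204800
#' @export
resnetHeadShapes <- function(inputSide) {
  inputSide <- as.integer(inputSide)
  if (inputSide < 32L)
    stop("inputSide must be >= 32 for the five stride-2 stages")
  convOut <- function(s, k, stride, pad) (s + 2L * pad - k) %/% stride + 1L
  side <- inputSide
  rows <- data.frame(stage = "input", side = side, channels = 3L)
  side <- convOut(side, 7L, 2L, 3L)
  rows <- rbind(rows, data.frame(stage = "conv1 7x7/2", side = side,
                                 channels = 64L))
  side <- convOut(side, 3L, 2L, 1L)
  rows <- rbind(rows, data.frame(stage = "maxpool 3x3/2", side = side,
                                 channels = 64L))
  ch <- c(256L, 512L, 1024L, 2048L)
  for (st in seq_along(.RESNET101_STAGES)) {
    if (st > 1L) side <- convOut(side, 3L, 2L, 1L)
    rows <- rbind(rows, data.frame(
      stage = sprintf("stage%d (%d blocks)", st, .RESNET101_STAGES[st]),
      side = side, channels = ch[st]))
  }
  rows
}

#' @rdname resnetHeadShapes
#' @return `resnetHeadFlattenSize`: the flattened feature length (final
#'   side squared times 2048).
#' @export
resnetHeadFlattenSize <- function(inputSide) {
  sh <- resnetHeadShapes(inputSide)
  last <- sh[nrow(sh), ]
  as.integer(last$side^2 * last$channels)
}

#' @rdname resnetHeadShapes
#' @return `resnetLayerCount`: the weighted-layer count, 101.
#' @export
resnetLayerCount <- function() {
  1L + 3L * sum(.RESNET101_STAGES) + 1L
}

#' Construct a TrainingConfig
#'
#' @param batchSize mini-batch size (default 32).
#' @param epochs training epochs.
#' @param learningRate optimizer step size.
#' @param optimizer "Adam" (default), "SGD" or "RMSprop".
#' @param splitRatio train fraction for [splitDataset()] (default 0.7).
#' @param seed seeds weight initialization, shuffling and dropout.
#' @return A [TrainingConfig-class].
#' @export
trainingConfig <- function(batchSize = 32L, epochs = 200L,
                           learningRate = 1e-3, optimizer = "Adam",
                           splitRatio = 0.7, seed = 0L) {
  new("TrainingConfig", batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), learningRate = learningRate,
      optimizer = optimizer, splitRatio = splitRatio,
      seed = as.integer(seed))
}

#' Build the classifier with freshly initialized weights
#'
#' Instantiates the architecture as real weight matrices (Glorot-uniform,
#' seeded) without training. The built model's layer shapes, reported from
#' the allocated matrices by [modelLayerShapes()], always agree with the
#' analytic [computeLayerShapes()].
#'
#' @param arch a [CNNArchitecture-class].
#' @param seed initialization seed.
#' @return An untrained [CNNModel-class].
#' @examples
#' m <- buildCNN(cnnArchitecture(inputSide = 32L, convFilters = c(4L, 8L)))
#' modelLayerShapes(m)
#' @export
buildCNN <- function(arch = cnnArchitecture(), seed = 0L) {
  stopifnot(is(arch, "CNNArchitecture"))
  validObject(arch)
  w <- .cpp_cnn_init(arch@inputSide, arch@inputSide, arch@channels,
                     arch@convFilters, arch@kernelSize, arch@denseUnits,
                     as.integer(seed))
  new("CNNModel", architecture = arch, weights = w, trained = FALSE,
      history = data.frame(), trainingSeconds = NA_real_,
      diverged = FALSE, config = NULL)
}

#' Backend-reported layer shapes of a built model
#'
#' Runs the compiled network code's own dimension bookkeeping (the actual
#' allocated matrix extents, not the analytic formula) and returns one row
#' per layer.
#'
#' @param model a [CNNModel-class].
#' @return A data.frame with columns `layer`, `side`, `units` in the same
#'   layout as [computeLayerShapes()].
#' @export
modelLayerShapes <- function(model) {
  stopifnot(is(model, "CNNModel"))
  a <- model@architecture
  d <- .cpp_cnn_layer_dims(a@inputSide, a@inputSide, a@channels,
                           a@convFilters, a@kernelSize, a@denseUnits)
  nb <- length(a@convFilters)
  layer <- c(rep(c("conv2d", "maxpool"), nb), "flatten", "dense", "dropout",
             "dense")
  side <- ifelse(seq_len(nrow(d)) <= 2L * nb, d[, 1], NA_integer_)
  units <- ifelse(seq_len(nrow(d)) <= 2L * nb, d[, 1] * d[, 2] * d[, 3],
                  d[, 1])
  data.frame(layer = layer, side = as.integer(side),
             units = as.integer(units))
}

.OPT_CODES <- c(Adam = 0L, SGD = 1L, RMSprop = 2L)

# Coerce a LarvaDataset or (H,W,C,N) array to the integer array the
# compiled trainer consumes.
#' Stack a dataset into an image array
#'
#' @param x a [LarvaDataset-class] or an integer array (H, W, C, N).
#' @return An integer array (H, W, C, N) with values in [0, 255].
#' @export
asImageArray <- function(x) {
  if (is(x, "LarvaDataset")) {
    stopifnot(length(x) > 0L)
    d <- dim(x[[1L]]@grid)
    out <- array(0L, c(d, length(x)))
    for (i in seq_len(length(x))) out[, , , i] <- x[[i]]@grid
    out
  } else {
    stopifnot(is.array(x), length(dim(x)) == 4L)
    storage.mode(x) <- "integer"
    x
  }
}

#' Train the classifier
#'
#' Trains with binary cross-entropy on 8-bit images rescaled to [0, 1].
#' Weight initialization, per-epoch shuffling and dropout are all seeded
#' from `config@seed`, so a (data, config) pair reproduces its run
#' bit-exactly on the same numerics library. A non-finite loss stops the
#' run and marks the model diverged rather than raising an error, so a
#' grid search can rank it last and continue.
#'
#' @param x training images: a [LarvaDataset-class] or integer array
#'   (H, W, C, N).
#' @param y binary labels (0/1), taken from the dataset when `x` is one.
#' @param arch a [CNNArchitecture-class]; defaults to the input's
#'   dimensions with the canonical filter stack.
#' @param config a [TrainingConfig-class].
#' @param validation optional list(x =, y =) evaluated after every epoch.
#' @return A trained [CNNModel-class] with per-epoch history and
#'   wall-clock `trainingSeconds`.
#' @export
trainCNN <- function(x, y = NULL, arch = NULL,
                     config = trainingConfig(), validation = NULL) {
  if (is(x, "LarvaDataset")) {
    if (is.null(y)) y <- datasetLabels(x)
    x <- asImageArray(x)
  }
  stopifnot(length(dim(x)) == 4L, !is.null(y), length(y) == dim(x)[4])
  if (anyNA(y)) stop("labels must be 0/1 with no NA")
  validObject(config)
  if (is.null(arch))
    arch <- cnnArchitecture(inputSide = dim(x)[1], channels = dim(x)[3])
  validObject(arch)
  if (dim(x)[1] != arch@inputSide || dim(x)[3] != arch@channels)
    stop("image dimensions do not match the architecture")
  storage.mode(x) <- "integer"

  vx <- NULL; vdim <- NULL; vy <- NULL
  if (!is.null(validation)) {
    vx <- asImageArray(if (is(validation, "LarvaDataset")) validation
                       else validation$x)
    vy <- if (is(validation, "LarvaDataset")) datasetLabels(validation)
          else as.numeric(validation$y)
    vdim <- dim(vx)
  }

  t0 <- proc.time()[["elapsed"]]
  fit <- .cpp_cnn_train(x, dim(x), as.numeric(y), arch@convFilters,
                        arch@kernelSize, arch@denseUnits, arch@dropoutRate,
                        config@epochs, config@batchSize,
                        config@learningRate, 0.9, 0.999, 1e-7,
                        .OPT_CODES[[config@optimizer]], config@seed,
                        vx, vdim, vy)
  seconds <- proc.time()[["elapsed"]] - t0

  history <- data.frame(epoch = seq_len(config@epochs),
                        train_acc = fit$train_acc,
                        train_loss = fit$train_loss,
                        val_acc = fit$val_acc, val_loss = fit$val_loss)
  new("CNNModel", architecture = arch, weights = fit$weights,
      trained = TRUE, history = history, trainingSeconds = seconds,
      diverged = fit$diverged, config = config)
}

#' Predict presence probabilities
#'
#' @param object a trained (or built) [CNNModel-class].
#' @param newdata a [LarvaDataset-class] or integer array (H, W, C, N).
#' @param ... unused.
#' @return Numeric vector of larva-presence probabilities in [0, 1].
#' @export
setMethod("predict", "CNNModel", function(object, newdata, ...) {
  x <- asImageArray(newdata)
  a <- object@architecture
  if (dim(x)[1] != a@inputSide || dim(x)[3] != a@channels)
    stop("image dimensions do not match the model architecture")
  as.numeric(.cpp_cnn_predict(x, dim(x), object@weights, a@convFilters,
                              a@kernelSize, a@denseUnits))
})

#' Assess training stability from a model's history
#'
#' A run is "unstable" when it diverged to a non-finite loss, when the
#' loss ever exceeded four times its initial value (a blow-up), or when
#' the trailing quarter of training shows no net progress — its mean loss
#' is still above 90% of the first epoch's, the signature of a learning
#' rate so high the loss just oscillates around its starting plateau.
#' High rates (0.05, 0.1) typically trip this; rates up to 1e-2 converge.
#'
#' @param model a trained [CNNModel-class].
#' @return `"stable"` or `"unstable"`.
#' @export
trainingStability <- function(model) {
  stopifnot(is(model, "CNNModel"), model@trained)
  if (model@diverged) return("unstable")
  loss <- model@history$train_loss
  loss <- loss[!is.na(loss)]
  if (any(!is.finite(loss))) return("unstable")
  if (max(loss) > 4 * loss[1] + 1e-9) return("unstable")
  tailq <- loss[seq.int(max(1L, length(loss) - ceiling(length(loss) / 4) + 1L),
                        length(loss))]
  if (mean(tailq) > 0.9 * loss[1]) return("unstable")
  "stable"
}

#' Deterministic train/test partition
#'
#' Splits sample indices into a train set of exactly `floor(ratio * n)`
#' and its complement. Stratified mode apportions the train quota across
#' classes by largest remainder, keeping per-class skew at most 1.
#' Lineage-aware mode keeps all augmentation variants of one parent on the
#' same side of the split (guarding against leakage), at the cost of only
#' approximate size exactness.
#'
#' @param labels binary label vector (or a [LarvaDataset-class]).
#' @param ratio train fraction in (0, 1), default 0.7.
#' @param seed shuffle seed.
#' @param stratified stratify by label (default TRUE); errors if any class
#'   has fewer than 2 samples.
#' @param lineageAware group augmentation siblings (requires a dataset).
#' @return A list with integer index vectors `train` and `test`
#'   (disjoint, exhaustive).
#' @examples
#' splitIndices(rep(0:1, 5), ratio = 0.7, seed = 1)
#' @export
splitIndices <- function(labels, ratio = 0.7, seed = 0L, stratified = TRUE,
                         lineageAware = FALSE) {
  groups <- NULL
  if (is(labels, "LarvaDataset")) {
    info <- sampleInfo(labels)
    groups <- ifelse(is.na(info$parentId), info$sampleId, info$parentId)
    labels <- info$label
  }
  n <- length(labels)
  if (n == 0L) stop("empty dataset")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly in (0, 1)")
  nTrain <- floor(ratio * n)

  if (lineageAware) {
    if (is.null(groups)) stop("lineageAware splitting needs a LarvaDataset")
    ug <- unique(groups)
    ord <- withSeed(seed, sample(ug))
    sizes <- table(groups)[ord]
    takeGroups <- ord[cumsum(sizes) <= nTrain]
    train <- which(groups %in% takeGroups)
    return(list(train = sort(train), test = setdiff(seq_len(n), train)))
  }

  if (stratified) {
    strata <- split(seq_len(n), labels)
    if (any(lengths(strata) < 2L))
      stop("every class needs at least 2 samples for a stratified split")
    quota <- vapply(strata, function(s) ratio * length(s), numeric(1))
    base <- floor(quota)
    rem <- nTrain - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    train <- withSeed(seed, unlist(Map(function(s, k) {
      if (k == 0) integer() else sample(s)[seq_len(k)]
    }, strata, base), use.names = FALSE))
  } else {
    train <- withSeed(seed, sample(n)[seq_len(nTrain)])
  }
  list(train = sort(train), test = setdiff(seq_len(n), sort(train)))
}

#' @rdname splitIndices
#' @param dataset a [LarvaDataset-class].
#' @return `splitDataset`: a list of two [LarvaDataset-class] objects,
#'   `train` and `test`.
#' @export
splitDataset <- function(dataset, ratio = 0.7, seed = 0L, stratified = TRUE,
                         lineageAware = FALSE) {
  stopifnot(is(dataset, "LarvaDataset"))
  idx <- splitIndices(dataset, ratio = ratio, seed = seed,
                      stratified = stratified, lineageAware = lineageAware)
  list(train = dataset[idx$train], test = dataset[idx$test])
}

#' Hyperparameter grid search
#'
#' Trains one model per (epochs, learning rate) combination — eight runs
#' under the canonical grid of epochs \{200, 300\} x rates \{1e-5, 1e-4,
#' 1e-3, 1e-2\} — on a fixed train/validation split, and ranks runs by
#' validation accuracy (descending) with validation loss (ascending) as
#' tie-break; diverged runs rank last. The grid is configurable so
#' scaled-down protocols can run the same code.
#'
#' @param x,y training images and labels (as in [trainCNN()]).
#' @param validation list(x =, y =) or [LarvaDataset-class]; required.
#' @param epochsGrid integer vector of epoch counts.
#' @param lrGrid numeric vector of learning rates.
#' @param arch a [CNNArchitecture-class] (default derived from the data).
#' @param baseConfig a [TrainingConfig-class] supplying batch size,
#'   optimizer and seed.
#' @param keepModels keep every trained model (memory-heavy) or only the
#'   best (default).
#' @return A list with `results` (data.frame: epochs, learning_rate,
#'   val_acc, val_loss, train_seconds, diverged, rank — row order follows
#'   the grid, `rank` gives the ordering), `best` (row index of the
#'   winner) and `models` (the winner, or all models when `keepModels`).
#' @export
gridSearch <- function(x, y = NULL, validation,
                       epochsGrid = c(200L, 300L),
                       lrGrid = c(1e-5, 1e-4, 1e-3, 1e-2),
                       arch = NULL, baseConfig = trainingConfig(),
                       keepModels = FALSE) {
  grid <- expand.grid(learning_rate = lrGrid, epochs = epochsGrid,
                      KEEP.OUT.ATTRS = FALSE)[, c("epochs", "learning_rate")]
  models <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- trainingConfig(batchSize = baseConfig@batchSize,
                          epochs = grid$epochs[i],
                          learningRate = grid$learning_rate[i],
                          optimizer = baseConfig@optimizer,
                          splitRatio = baseConfig@splitRatio,
                          seed = baseConfig@seed)
    fit <- trainCNN(x, y, arch = arch, config = cfg, validation = validation)
    h <- fit@history
    ok <- which(!is.na(h$val_acc))
    last <- if (length(ok)) h[max(ok), ] else
      data.frame(val_acc = NA_real_, val_loss = NA_real_)
    rows[[i]] <- data.frame(epochs = grid$epochs[i],
                            learning_rate = grid$learning_rate[i],
                            val_acc = last$val_acc, val_loss = last$val_loss,
                            train_seconds = fit@trainingSeconds,
                            diverged = fit@diverged)
    models[[i]] <- fit
  }
  results <- do.call(rbind, rows)
  ord <- order(results$diverged,            # healthy runs first
               -replace(results$val_acc, is.na(results$val_acc), -Inf),
               replace(results$val_loss, is.na(results$val_loss), Inf))
  results$rank <- NA_integer_
  results$rank[ord] <- seq_len(nrow(results))
  best <- which(results$rank == 1L)
  list(results = results, best = best,
       models = if (keepModels) models else models[[best]])
}
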