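#' Spectral band definitions of the multispectral camera
#'
#' The four-band layout of the Parrot Sequoia-class camera the pipeline
#' assumes: green (GRE, 550/40 nm), red (RED, 660/40 nm), red edge
#' (REG, 735/10 nm) and near-infrared (NIR, 790/40 nm).
#'
#' @return A data.frame with columns `name`, `center_nm`, `bandwidth_nm`,
#'   one row per band, in the fixed band order used for deterministic
#'   tie-breaking throughout the package: GRE, NIR, RED, REG.
#' @examples
#' spectralBands()
#' @export
spectralBands <- function() {
  data.frame(
    name = c("GRE", "NIR", "RED", "REG"),
    center_nm = c(550, 790, 660, 735),
    bandwidth_nm = c(40, 40, 40, 10),
    stringsAsFactors = FALSE
  )
}

.BANDS <- c("GRE", "NIR", "RED", "REG")
.SPECIES <- c("chironomid", "yellow_worm", "mosquito")

#' SceneSpec: geometry and radiometry of one synthetic multispectral scene
#'
#' Describes a single capture for the synthetic generator: image side,
#' larva geometry (an elongated capsule: length, width, orientation,
#' optional curvature bow), per-band contrast lift of the larva over the
#' background, background level, additive noise, and the species profile.
#'
#' Invariants enforced by the validity method:
#' * the larva bounding box fits a 100x100 window (length + width +
#'   curvature bow <= 100), matching the observed larva scale;
#' * the GRE contrast is strictly the largest (GRE is the band where
#'   larvae are most recognizable);
#' * width < length (narrow, elongated shape).
#'
#' @slot imageSide integer, image side in px (default 1200).
#' @slot larvaLength,larvaWidth numeric, capsule dimensions in px.
#' @slot larvaOrientation numeric, degrees.
#' @slot larvaCurvature numeric, perpendicular bow of the centerline in px.
#' @slot larvaCenter numeric length-2, 0-based (row, col) of the capsule center.
#' @slot bandContrast named numeric over GRE/NIR/RED/REG in [0, 1]; the
#'   larva's intensity lift is `bandContrast * 255` before noise.
#' @slot backgroundLevel numeric, mean background intensity (8-bit units).
#' @slot noiseSd numeric, standard deviation of additive Gaussian noise.
#' @slot larvaPresent logical.
#' @slot speciesProfile one of "chironomid", "yellow_worm", "mosquito".
#' @aliases SceneSpec
#' @seealso [sceneSpec()], [generateCapture()]
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  imageSide = "integer",
  larvaLength = "numeric",
  larvaWidth = "numeric",
  larvaOrientation = "numeric",
  larvaCurvature = "numeric",
  larvaCenter = "numeric",
  bandContrast = "numeric",
  backgroundLevel = "numeric",
  noiseSd = "numeric",
  larvaPresent = "logical",
  speciesProfile = "character"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@imageSide < 1L) msg <- c(msg, "imageSide must be positive")
  if (!identical(sort(names(object@bandContrast)), sort(.BANDS)))
    msg <- c(msg, "bandContrast must be named over GRE, NIR, RED, REG")
  else {
    if (any(object@bandContrast < 0 | object@bandContrast > 1))
      msg <- c(msg, "bandContrast values must lie in [0, 1]")
    others <- object@bandContrast[setdiff(.BANDS, "GRE")]
    if (!all(object@bandContrast[["GRE"]] > others))
      msg <- c(msg, "GRE contrast must be strictly greater than every other band")
  }
  if (object@larvaWidth >= object@larvaLength)
    msg <- c(msg, "larvaWidth must be strictly less than larvaLength")
  if (object@larvaLength + object@larvaWidth + abs(object@larvaCurvature) > 100)
    msg <- c(msg, "larva bounding box must fit within a 100x100 window")
  if (length(object@larvaCenter) != 2L)
    msg <- c(msg, "larvaCenter must have length 2")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (!object@speciesProfile %in% .SPECIES)
    msg <- c(msg, sprintf("speciesProfile must be one of: %s",
                          paste(.SPECIES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' MultispectralCapture: one scene as four co-registered band images
#'
#' Holds the four 8-bit band grids (integer matrices in [0, 255], identical
#' dimensions, keyed GRE/NIR/RED/REG), the ground-truth [SceneSpec-class]
#' when the capture is synthetic, and an opaque capture identifier.
#'
#' @slot bands named list of integer matrices.
#' @slot truth a [SceneSpec-class], or `NULL` for captures without truth.
#' @slot captureId character scalar.
#' @aliases MultispectralCapture
#' @seealso [generateCapture()], [bandImage()], [captureId()]
#' @exportClass MultispectralCapture
setClass("MultispectralCapture", representation(
  bands = "list",
  truth = "ANY",
  captureId = "character"
))

setValidity("MultispectralCapture", function(object) {
  msg <- character()
  if (!identical(sort(names(object@bands)), sort(.BANDS)))
    msg <- c(msg, "bands must be a named list over GRE, NIR, RED, REG")
  else {
    dims <- lapply(object@bands, dim)
    if (length(unique(dims)) != 1L)
      msg <- c(msg, "all band grids must share identical dimensions")
    rng <- range(vapply(object@bands, range, numeric(2)))
    if (rng[1] < 0 || rng[2] > 255)
      msg <- c(msg, "band pixel values must lie in [0, 255]")
  }
  if (!(is.null(object@truth) || is(object@truth, "SceneSpec")))
    msg <- c(msg, "truth must be NULL or a SceneSpec")
  if (length(object@captureId) != 1L)
    msg <- c(msg, "captureId must be a single string")
  if (length(msg)) msg else TRUE
})

#' WaveletImage: a band image after 2-D wavelet conversion
#'
#' The approximation subband of a separable 2-D discrete wavelet transform,
#' rescaled to 8-bit, together with its fixed-colormap 3-channel rendering
#' (the input to RGB channel separation). The rendering is a pure function
#' of the grid: G equals the grid value and R = B = 255 - grid, so the green
#' channel is monotonically increasing in wavelet intensity (the package's
#' colormap contract) while R and B mirror it.
#'
#' @slot sourceBand band name, or `NA` when built from a bare matrix.
#' @slot grid integer matrix in [0, 255].
#' @slot rgb integer array (rows x cols x 3) in [0, 255].
#' @slot waveletFamily "haar" or "db2".
#' @slot level integer decomposition level (>= 1).
#' @aliases WaveletImage
#' @seealso [waveletTransform()], [splitChannels()]
#' @exportClass WaveletImage
setClass("WaveletImage", representation(
  sourceBand = "character",
  grid = "matrix",
  rgb = "array",
  waveletFamily = "character",
  level = "integer"
))

setValidity("WaveletImage", function(object) {
  msg <- character()
  if (!identical(dim(object@rgb), c(dim(object@grid), 3L)))
    msg <- c(msg, "rgb dimensions must equal grid dimensions with 3 channels")
  if (min(object@grid) < 0 || max(object@grid) > 255)
    msg <- c(msg, "grid values must lie in [0, 255]")
  if (object@level < 1L) msg <- c(msg, "level must be >= 1")
  if (!object@waveletFamily %in% c("haar", "db2"))
    msg <- c(msg, "waveletFamily must be 'haar' or 'db2'")
  if (length(msg)) msg else TRUE
})

#' SegmentedSample: a standardized larva-centered crop
#'
#' A 300x300 3-channel 8-bit crop taken from a wavelet rendering, with its
#' binary label (1 = larva present, 0 = absent, NA when the source capture
#' has no truth), species profile, 0-based crop origin in the source image,
#' source capture id, and augmentation lineage (parent sample id and the
#' draw seed that regenerates the variant bit-exactly).
#'
#' @slot grid integer array 300 x 300 x 3 in [0, 255].
#' @slot label integer 0/1 or NA.
#' @slot species species profile string.
#' @slot cropOrigin integer length-2, 0-based (row, col) of the crop's
#'   top-left corner in the source image.
#' @slot sourceCapture character capture id.
#' @slot sampleId character.
#' @slot parentId character, NA for originals.
#' @slot drawSeed integer, NA for originals.
#' @aliases SegmentedSample
#' @seealso [segmentCaptures()], [augmentImage()]
#' @exportClass SegmentedSample
setClass("SegmentedSample", representation(
  grid = "array",
  label = "integer",
  species = "character",
  cropOrigin = "integer",
  sourceCapture = "character",
  sampleId = "character",
  parentId = "character",
  drawSeed = "integer"
))

.CROP_SIDE <- 300L

setValidity("SegmentedSample", function(object) {
  msg <- character()
  if (!identical(dim(object@grid), c(.CROP_SIDE, .CROP_SIDE, 3L)))
    msg <- c(msg, "grid must be exactly 300 x 300 x 3")
  else if (min(object@grid) < 0 || max(object@grid) > 255)
    msg <- c(msg, "grid values must lie in [0, 255]")
  if (!is.na(object@label) && !object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0, 1 or NA")
  if (length(object@cropOrigin) != 2L || any(object@cropOrigin < 0L, na.rm = TRUE))
    msg <- c(msg, "cropOrigin must be two non-negative 0-based coordinates")
  if (length(msg)) msg else TRUE
})

#' LarvaDataset: an ordered collection of segmented samples
#'
#' Wraps a list of [SegmentedSample-class] objects; labels, species and
#' augmentation lineage are reachable through [sampleInfo()]. Subsetting
#' with `[` keeps order, `length()` counts samples and `[[` extracts one
#' sample.
#'
#' @slot samples list of [SegmentedSample-class].
#' @aliases LarvaDataset
#' @seealso [segmentCaptures()], [augmentDataset()], [splitDataset()]
#' @exportClass LarvaDataset
setClass("LarvaDataset", representation(samples = "list"))

setValidity("LarvaDataset", function(object) {
  ok <- vapply(object@samples, function(s) is(s, "SegmentedSample"), logical(1))
  if (all(ok)) TRUE else "all elements must be SegmentedSample objects"
})

#' CNNArchitecture: the compact convolutional classifier layout
#'
#' The 10-layer binary classifier: three blocks of 3x3 unpadded convolution
#' (16, 32, 64 filters, ReLU) each followed by 2x2 max pooling, then
#' flatten, a dense ReLU layer (256 or 512 units), 50% dropout and a single
#' sigmoid output unit. The default instance reproduces the canonical
#' layout for 300x300 3-channel inputs; filters, kernel, dense width and
#' input side are configurable for scaled-down experiments.
#'
#' @slot inputSide integer, input image side in px.
#' @slot channels integer, input channels.
#' @slot convFilters integer vector of filters per block.
#' @slot kernelSize integer, square kernel side.
#' @slot denseUnits integer.
#' @slot dropoutRate numeric in [0, 1).
#' @aliases CNNArchitecture
#' @seealso [cnnArchitecture()], [computeLayerShapes()], [buildCNN()]
#' @exportClass CNNArchitecture
setClass("CNNArchitecture", representation(
  inputSide = "integer",
  channels = "integer",
  convFilters = "integer",
  kernelSize = "integer",
  denseUnits = "integer",
  dropoutRate = "numeric"
))

setValidity("CNNArchitecture", function(object) {
  msg <- character()
  if (object@inputSide < object@kernelSize)
    msg <- c(msg, "inputSide must be at least kernelSize")
  if (length(object@convFilters) < 1L || any(object@convFilters < 1L))
    msg <- c(msg, "convFilters must be a non-empty positive integer vector")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (object@channels < 1L) msg <- c(msg, "channels must be positive")
  if (length(msg)) msg else TRUE
})

#' TrainingConfig: hyperparameters of one training run
#'
#' Defaults follow the tuning protocol: batch size 32, Adam, a 7:3
#' train/test split; epochs from \{200, 300\} and learning rates from
#' \{1e-5, 1e-4, 1e-3, 1e-2\} are the grid-search axes.
#'
#' @slot batchSize integer.
#' @slot epochs integer.
#' @slot learningRate numeric.
#' @slot optimizer "Adam", "SGD" or "RMSprop".
#' @slot splitRatio numeric in (0, 1).
#' @slot seed integer, seeds weight init, shuffling and dropout.
#' @aliases TrainingConfig
#' @seealso [trainingConfig()], [trainCNN()], [gridSearch()]
#' @exportClass TrainingConfig
setClass("TrainingConfig", representation(
  batchSize = "integer",
  epochs = "integer",
  learningRate = "numeric",
  optimizer = "character",
  splitRatio = "numeric",
  seed = "integer"
))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (!object@optimizer %in% c("Adam", "SGD", "RMSprop"))
    msg <- c(msg, "optimizer must be Adam, SGD or RMSprop")
  if (object@splitRatio <= 0 || object@splitRatio >= 1)
    msg <- c(msg, "splitRatio must lie strictly between 0 and 1")
  if (length(msg)) msg else TRUE
})

#' CNNModel: a built (and possibly trained) convolutional classifier
#'
#' Produced untrained by [buildCNN()] and trained by [trainCNN()]. Holds
#' the architecture, the weight matrices, the per-epoch history (training
#' and, when validation data were supplied, validation accuracy and loss),
#' the wall-clock training duration and the [TrainingConfig-class] used.
#'
#' @slot architecture a [CNNArchitecture-class].
#' @slot weights list of weight matrices.
#' @slot trained logical.
#' @slot history data.frame with columns epoch, train_acc, train_loss,
#'   val_acc, val_loss (one row per configured epoch; rows after a
#'   divergence stop are NA).
#' @slot trainingSeconds numeric.
#' @slot diverged logical, TRUE when training hit a non-finite loss.
#' @slot config a [TrainingConfig-class] or NULL.
#' @aliases CNNModel
#' @seealso [buildCNN()], [trainCNN()], [predict,CNNModel-method]
#' @exportClass CNNModel
setClass("CNNModel", representation(
  architecture = "CNNArchitecture",
  weights = "list",
  trained = "logical",
  history = "data.frame",
  trainingSeconds = "numeric",
  diverged = "logical",
  config = "ANY"
))

#' AugmentationPolicy: seeded geometric augmentation parameters
#'
#' Random rotations, horizontal/vertical shifts, horizontal flips and
#' zooming in/out, with an expansion `factor` (output size = factor x
#' input size, originals included). All draws derive from `seed`, so each
#' variant is regenerable from its recorded lineage.
#'
#' @slot rotationRange numeric, degrees (draw is uniform in +/- range).
#' @slot shiftRange numeric, fraction of the side.
#' @slot horizontalFlip logical, flip with probability 0.5 when TRUE.
#' @slot zoomRange numeric fraction; zoom factor uniform in [1 - z, 1 + z].
#' @slot factor integer >= 1.
#' @slot seed integer.
#' @aliases AugmentationPolicy
#' @seealso [augmentationPolicy()], [augmentDataset()]
#' @exportClass AugmentationPolicy
setClass("AugmentationPolicy", representation(
  rotationRange = "numeric",
  shiftRange = "numeric",
  horizontalFlip = "logical",
  zoomRange = "numeric",
  factor = "integer",
  seed = "integer"
))

setValidity("AugmentationPolicy", function(object) {
  msg <- character()
  if (object@factor < 1L) msg <- c(msg, "factor must be >= 1")
  if (object@rotationRange < 0 || object@shiftRange < 0 || object@zoomRange < 0)
    msg <- c(msg, "ranges must be non-negative")
  if (object@zoomRange >= 1) msg <- c(msg, "zoomRange must be < 1")
  if (length(msg)) msg else TRUE
})

#' EvalReport: per-model evaluation metrics
#'
#' Accuracy, precision, recall, F1, the 2x2 confusion matrix, the
#' probability root-mean-square error against the binary labels, and
#' wall-clock training seconds. Confusion counts always sum to `nEval`
#' and accuracy equals (TP + TN) / nEval exactly.
#'
#' @slot modelId character.
#' @slot accuracy,precision,recall,f1 numeric fractions in [0, 1].
#' @slot confusion 2x2 integer matrix (rows = truth, cols = prediction).
#' @slot rmse non-negative numeric.
#' @slot trainingSeconds numeric (NA when unknown).
#' @slot nEval integer.
#' @aliases EvalReport
#' @seealso [classificationMetrics()], [selectOptimal()]
#' @exportClass EvalReport
setClass("EvalReport", representation(
  modelId = "character",
  accuracy = "numeric",
  precision = "numeric",
  recall = "numeric",
  f1 = "numeric",
  confusion = "matrix",
  rmse = "numeric",
  trainingSeconds = "numeric",
  nEval = "integer"
))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (sum(object@confusion) != object@nEval)
    msg <- c(msg, "confusion counts must sum to nEval")
  acc <- (object@confusion[1, 1] + object@confusion[2, 2]) / object@nEval
  if (object@nEval > 0 && abs(acc - object@accuracy) > 1e-12)
    msg <- c(msg, "accuracy must equal (TP + TN) / nEval")
  if (object@rmse < 0) msg <- c(msg, "rmse must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SelectionVerdict: the optimal-model decision
#'
#' Records the full ranking of candidate models under the real-time
#' selection rule (accuracy floor, then training speed, then RMSE), the
#' selected model id and whether any candidate met the accuracy floor.
#'
#' @slot selected character model id.
#' @slot ranking data.frame with one row per candidate in rank order.
#' @slot accuracyFloor numeric.
#' @slot floorMet logical; FALSE means the verdict fell back to the
#'   best-accuracy candidate and carries a warning flag.
#' @aliases SelectionVerdict
#' @seealso [selectOptimal()]
#' @exportClass SelectionVerdict
setClass("SelectionVerdict", representation(
  selected = "character",
  ranking = "data.frame",
  accuracyFloor = "numeric",
  floorMet = "logical"
))
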