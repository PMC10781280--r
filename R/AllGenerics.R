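#' @name larvaDetect-generics
#' @title Generics and accessors for larvaDetect classes
#' @description Accessor generics for the package's S4 classes. Slot access
#'   from user code should always go through these.
#' @param x,object an object of the documented class.
#' @param i index.
#' @param band band name (one of GRE, NIR, RED, REG).
#' @param ... passed on to methods.
NULL

#' @rdname larvaDetect-generics
#' @export
setGeneric("bandImage", function(x, band, ...) standardGeneric("bandImage"))

#' @rdname larvaDetect-generics
#' @export
setGeneric("captureId", function(x) standardGeneric("captureId"))

#' @rdname larvaDetect-generics
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' @rdname larvaDetect-generics
#' @export
setGeneric("waveletGrid", function(x) standardGeneric("waveletGrid"))

#' @rdname larvaDetect-generics
#' @export
setGeneric("waveletRGB", function(x) standardGeneric("waveletRGB"))

#' @rdname larvaDetect-generics
#' @export
setGeneric("sampleGrid", function(x) standardGeneric("sampleGrid"))

#' @rdname larvaDetect-generics
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @rdname larvaDetect-generics
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname larvaDetect-generics
#' @export
setGeneric("datasetLabels", function(x) standardGeneric("datasetLabels"))

#' @rdname larvaDetect-generics
#' @export
setGeneric("modelHistory", function(x) standardGeneric("modelHistory"))

#' @rdname larvaDetect-generics
#' @export
setGeneric("trainingSeconds", function(x) standardGeneric("trainingSeconds"))

# ---- MultispectralCapture ----

#' @rdname larvaDetect-generics
#' @export
setMethod("bandImage", "MultispectralCapture", function(x, band) {
  band <- match.arg(band, .BANDS)
  x@bands[[band]]
})

#' @rdname larvaDetect-generics
#' @export
setMethod("captureId", "MultispectralCapture", function(x) x@captureId)

#' @rdname larvaDetect-generics
#' @export
setMethod("sceneTruth", "MultispectralCapture", function(x) x@truth)

setMethod("show", "MultispectralCapture", function(object) {
  d <- dim(object@bands[[1]])
  cat(sprintf("MultispectralCapture '%s': %d x %d px, bands %s\n",
              object@captureId, d[1], d[2],
              paste(names(object@bands), collapse = "/")))
  if (is.null(object@truth)) {
    cat("  truth: none\n")
  } else {
    cat(sprintf("  truth: larva %s (%s)\n",
                if (object@truth@larvaPresent) "present" else "absent",
                object@truth@speciesProfile))
  }
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d px %s scene, larva %s\n",
              object@imageSide, object@speciesProfile,
              if (object@larvaPresent) "present" else "absent"))
  if (object@larvaPresent)
    cat(sprintf("  capsule %.0f x %.0f px at (%.0f, %.0f), %.0f deg\n",
                object@larvaLength, object@larvaWidth,
                object@larvaCenter[1], object@larvaCenter[2],
                object@larvaOrientation))
  cat(sprintf("  background %.0f, noise sd %.1f, GRE contrast %.2f\n",
              object@backgroundLevel, object@noiseSd,
              object@bandContrast[["GRE"]]))
})

# ---- WaveletImage ----

#' @rdname larvaDetect-generics
#' @export
setMethod("waveletGrid", "WaveletImage", function(x) x@grid)

#' @rdname larvaDetect-generics
#' @export
setMethod("waveletRGB", "WaveletImage", function(x) x@rgb)

setMethod("show", "WaveletImage", function(object) {
  d <- dim(object@grid)
  cat(sprintf("WaveletImage (%s, level %d) from band %s: %d x %d px\n",
              object@waveletFamily, object@level, object@sourceBand,
              d[1], d[2]))
})

# ---- SegmentedSample / LarvaDataset ----

#' @rdname larvaDetect-generics
#' @export
setMethod("sampleGrid", "SegmentedSample", function(x) x@grid)

#' @rdname larvaDetect-generics
#' @export
setMethod("sampleLabel", "SegmentedSample", function(x) x@label)

setMethod("show", "SegmentedSample", function(object) {
  cat(sprintf("SegmentedSample '%s': 300 x 300 x 3, label %s, species %s\n",
              object@sampleId,
              ifelse(is.na(object@label), "NA", object@label),
              object@species))
  if (!is.na(object@parentId))
    cat(sprintf("  augmented from '%s' (draw seed %d)\n",
                object@parentId, object@drawSeed))
})

#' @rdname larvaDetect-generics
#' @export
setMethod("length", "LarvaDataset", function(x) length(x@samples))

#' @rdname larvaDetect-generics
#' @export
setMethod("[", "LarvaDataset", function(x, i) {
  new("LarvaDataset", samples = x@samples[i])
})

#' @rdname larvaDetect-generics
#' @export
setMethod("[[", "LarvaDataset", function(x, i) x@samples[[i]])

#' @rdname larvaDetect-generics
#' @export
setMethod("sampleInfo", "LarvaDataset", function(x) {
  data.frame(
    sampleId = vapply(x@samples, function(s) s@sampleId, character(1)),
    label = vapply(x@samples, function(s) s@label, integer(1)),
    species = vapply(x@samples, function(s) s@species, character(1)),
    sourceCapture = vapply(x@samples, function(s) s@sourceCapture, character(1)),
    parentId = vapply(x@samples, function(s) s@parentId, character(1)),
    drawSeed = vapply(x@samples, function(s) s@drawSeed, integer(1)),
    stringsAsFactors = FALSE
  )
})

#' @rdname larvaDetect-generics
#' @export
setMethod("datasetLabels", "LarvaDataset", function(x) {
  vapply(x@samples, function(s) s@label, integer(1))
})

setMethod("show", "LarvaDataset", function(object) {
  lab <- datasetLabels(object)
  cat(sprintf("LarvaDataset: %d samples (%d present, %d absent, %d unlabelled)\n",
              length(object), sum(lab == 1L, na.rm = TRUE),
              sum(lab == 0L, na.rm = TRUE), sum(is.na(lab))))
})

# ---- CNNModel ----

#' @rdname larvaDetect-generics
#' @export
setMethod("modelHistory", "CNNModel", function(x) x@history)

#' @rdname larvaDetect-generics
#' @export
setMethod("trainingSeconds", "CNNModel", function(x) x@trainingSeconds)

setMethod("show", "CNNModel", function(object) {
  a <- object@architecture
  cat(sprintf("CNNModel: input %d x %d x %d, conv filters %s, dense %d\n",
              a@inputSide, a@inputSide, a@channels,
              paste(a@convFilters, collapse = "/"), a@denseUnits))
  if (object@trained) {
    h <- object@history
    last <- h[max(which(!is.na(h$train_loss))), ]
    cat(sprintf("  trained %d epochs in %.1f s; final train acc %.3f",
                nrow(h), object@trainingSeconds, last$train_acc))
    if (!is.na(last$val_acc)) cat(sprintf(", val acc %.3f", last$val_acc))
    cat("\n")
    if (object@diverged) cat("  WARNING: training diverged (non-finite loss)\n")
  } else {
    cat("  untrained\n")
  }
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport '%s' (n = %d)\n", object@modelId, object@nEval))
  cat(sprintf("  accuracy %.4f, precision %.4f, recall %.4f, F1 %.4f\n",
              object@accuracy, object@precision, object@recall, object@f1))
  cat(sprintf("  probability RMSE %.4g, training %.1f s\n",
              object@rmse, object@trainingSeconds))
})

setMethod("show", "SelectionVerdict", function(object) {
  cat(sprintf("SelectionVerdict: '%s' selected (accuracy floor %.2f%s)\n",
              object@selected, object@accuracyFloor,
              if (object@floorMet) "" else "; WARNING: floor not met"))
  print(object@ranking)
})
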