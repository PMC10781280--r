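# Image and manifest writers. EBImage indexes images (x, y) = (col, row),
# so grids are transposed on the way in/out to keep the package's
# row/column convention intact across round-trips.

#' Write a capture's band images and truth sidecar
#'
#' Writes one image per band named `<captureId>_<BAND>.<format>`, plus a
#' JSON sidecar `<captureId>_truth.json` describing the ground-truth scene
#' when present, and returns the paths.
#'
#' @param capture a [MultispectralCapture-class].
#' @param dir output directory (created if missing).
#' @param format "tiff" or "png".
#' @return Invisibly, a character vector of written paths.
#' @export
writeCaptureImages <- function(capture, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") "tif" else "png"
  paths <- character()
  for (b in names(capture@bands)) {
    p <- file.path(dir, sprintf("%s_%s.%s", captureId(capture), b, ext))
    EBImage::writeImage(EBImage::Image(t(capture@bands[[b]]) / 255), p)
    paths <- c(paths, p)
  }
  truth <- sceneTruth(capture)
  if (!is.null(truth)) {
    p <- file.path(dir, sprintf("%s_truth.json", captureId(capture)))
    jsonlite::write_json(
      list(imageSide = truth@imageSide, larvaPresent = truth@larvaPresent,
           speciesProfile = truth@speciesProfile,
           larvaLength = truth@larvaLength, larvaWidth = truth@larvaWidth,
           larvaOrientation = truth@larvaOrientation,
           larvaCurvature = truth@larvaCurvature,
           larvaCenter = truth@larvaCenter,
           bandContrast = as.list(truth@bandContrast),
           backgroundLevel = truth@backgroundLevel, noiseSd = truth@noiseSd),
      p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a capture back from band images
#'
#' Inverse of [writeCaptureImages()]: reads the four band images (and the
#' truth sidecar if present) for `captureId` from `dir`.
#'
#' @param dir directory holding the images.
#' @param captureId the capture identifier used when writing.
#' @param format "tiff" or "png".
#' @return A [MultispectralCapture-class].
#' @export
readCaptureImages <- function(dir, captureId, format = c("tiff", "png")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  bands <- lapply(setNames(.BANDS, .BANDS), function(b) {
    p <- file.path(dir, sprintf("%s_%s.%s", captureId, b, ext))
    img <- EBImage::readImage(p)
    m <- t(EBImage::imageData(img)) * 255
    matrix(as.integer(round(m)), nrow(m), ncol(m))
  })
  truthPath <- file.path(dir, sprintf("%s_truth.json", captureId))
  truth <- NULL
  if (file.exists(truthPath)) {
    tj <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
    truth <- sceneSpec(imageSide = tj$imageSide,
                       larvaLength = tj$larvaLength,
                       larvaWidth = tj$larvaWidth,
                       larvaOrientation = tj$larvaOrientation,
                       larvaCurvature = tj$larvaCurvature,
                       larvaCenter = tj$larvaCenter,
                       bandContrast = unlist(tj$bandContrast)[.BANDS],
                       backgroundLevel = tj$backgroundLevel,
                       noiseSd = tj$noiseSd,
                       larvaPresent = tj$larvaPresent,
                       speciesProfile = tj$speciesProfile)
  }
  new("MultispectralCapture", bands = bands, truth = truth,
      captureId = captureId)
}

#' Write one segmented sample as a PNG
#'
#' Stored under `dir/<species>/<label>/<sampleId>.png`, mirroring how a
#' class-labelled training corpus is laid out on disk.
#'
#' @param sample a [SegmentedSample-class].
#' @param dir root output directory.
#' @return Invisibly, the written path.
#' @export
writeSampleImage <- function(sample, dir) {
  sub <- file.path(dir, sample@species,
                   ifelse(is.na(sample@label), "unlabelled", sample@label))
  dir.create(sub, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(sub, paste0(sample@sampleId, ".png"))
  img <- EBImage::Image(aperm(sample@grid / 255, c(2, 1, 3)),
                        colormode = "Color")
  EBImage::writeImage(img, p)
  invisible(p)
}

#' Write a dataset manifest CSV
#'
#' One row per sample: id, label, species, source capture and augmentation
#' lineage (parent id and draw seed).
#'
#' @param dataset a [LarvaDataset-class].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeDatasetManifest <- function(dataset, path) {
  write.csv(sampleInfo(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Write a wavelet rendering as PNG
#'
#' Writes the 3-channel colormap rendering of a [WaveletImage-class], the
#' visual artifact of the preprocessing stage.
#'
#' @param wavelet a [WaveletImage-class].
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
writeWaveletImage <- function(wavelet, path) {
  stopifnot(is(wavelet, "WaveletImage"))
  img <- EBImage::Image(aperm(waveletRGB(wavelet) / 255, c(2, 1, 3)),
                        colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Write per-column distribution summaries as CSV
#'
#' @param x a matrix or [WaveletImage-class] passed to
#'   [columnDistribution()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeColumnSummary <- function(x, path) {
  write.csv(columnDistribution(x), path, row.names = FALSE)
  invisible(path)
}
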