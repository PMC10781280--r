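#' Split a 3-channel image into R, G, B planes
#'
#' Lossless channel separation: re-stacking the three returned planes along
#' the third dimension reproduces the input exactly.
#'
#' @param x an array with dimensions (rows, cols, 3), or a
#'   [WaveletImage-class] whose rendering is separated.
#' @return A named list of three matrices `R`, `G`, `B`.
#' @examples
#' planes <- splitChannels(array(1:24, c(2, 4, 3)))
#' names(planes)
#' @export
splitChannels <- function(x) {
  if (is(x, "WaveletImage")) x <- waveletRGB(x)
  d <- dim(x)
  if (length(d) != 3L || d[3] != 3L)
    stop(sprintf("expected a 3-channel image, got %s channels",
                 if (length(d) == 3L) d[3] else "a non-3-D array's"))
  list(R = x[, , 1], G = x[, , 2], B = x[, , 3])
}

#' Locate the larva at the green-channel intensity maximum
#'
#' Returns the 0-based (row, col) coordinate of the global maximum of the
#' given plane. When several pixels tie at the maximum, the smallest row
#' wins, then the smallest column; a constant plane therefore yields
#' (0, 0).
#'
#' @param gPlane a non-empty numeric/integer matrix, normally the G plane
#'   from [splitChannels()].
#' @return Integer vector `c(row, col)`, 0-based, top-left origin.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 2] <- 9
#' locateLarva(m)  # c(2, 1)
#' @export
locateLarva <- function(gPlane) {
  if (!is.matrix(gPlane) || length(gPlane) == 0L)
    stop("gPlane must be a non-empty matrix")
  idx <- which(gPlane == max(gPlane)) - 1L
  rows <- idx %% nrow(gPlane)
  cols <- idx %/% nrow(gPlane)
  rmin <- min(rows)
  c(row = rmin, col = min(cols[rows == rmin]))
}

#' Crop a fixed-size window centered on a coordinate
#'
#' Extracts a `size` x `size` crop nominally centered on `center` (0-based
#' row, col). A window that would overrun the image border is shifted
#' (clamped) to stay fully inside, never padded, so the output is always
#' exactly `size` x `size` of real pixels.
#'
#' @param image a matrix or (rows, cols, channels) array, at least
#'   `size` px in both spatial dimensions.
#' @param center 0-based (row, col) of the nominal crop center.
#' @param size crop side in px (default 300).
#' @return A list with `grid` (the crop, same channel structure as the
#'   input) and `origin` (0-based row, col of the crop's top-left corner
#'   in the source).
#' @examples
#' cropCentered(matrix(0, 400, 400), c(10, 10), size = 300)$origin  # c(0, 0)
#' @export
cropCentered <- function(image, center, size = 300L) {
  d <- dim(image)
  if (any(d[1:2] < size))
    stop(sprintf("image (%d x %d) is smaller than the %d px crop window",
                 d[1], d[2], size))
  origin <- vapply(1:2, function(k) {
    o <- round(center[k] - size / 2)
    min(max(o, 0), d[k] - size)
  }, numeric(1))
  ri <- origin[1] + seq_len(size)
  ci <- origin[2] + seq_len(size)
  grid <- if (length(d) == 3L) image[ri, ci, , drop = FALSE]
          else image[ri, ci, drop = FALSE]
  list(grid = grid, origin = as.integer(origin))
}

#' Segment captures into standardized larva-centered crops
#'
#' For each capture: converts the chosen band to its wavelet rendering,
#' separates channels, and scores the capture as
#' `max(G) - median(G)`. Captures scoring below `qualityThreshold` are
#' rejected (no feature stands out; this reproduces the attrition from raw
#' to segmented image counts) and logged; accepted captures yield one
#' [SegmentedSample-class] cropped from the full 3-channel rendering at
#' the G-plane maximum.
#'
#' Because wavelet conversion rescales each image to the full 8-bit range,
#' noisy larva-absent captures stretch their noise to that range and pass
#' the filter (becoming label-0 samples), while featureless near-constant
#' captures fail it.
#'
#' @param captures list of [MultispectralCapture-class].
#' @param qualityThreshold minimum `max(G) - median(G)` score (intensity
#'   units, default 50).
#' @param band band to segment from (default `"GRE"`).
#' @param family,level wavelet settings.
#' @param size crop side (default 300).
#' @return A list with `dataset` (a [LarvaDataset-class] of accepted
#'   samples) and `rejections` (data.frame: captureId, score, threshold,
#'   verdict for every capture).
#' @export
segmentCaptures <- function(captures, qualityThreshold = 50, band = "GRE",
                            family = "haar", level = 1L, size = 300L) {
  samples <- list()
  log <- data.frame(captureId = character(), score = numeric(),
                    threshold = numeric(), verdict = character(),
                    stringsAsFactors = FALSE)
  for (cp in captures) {
    res <- segmentCapture(cp, qualityThreshold = qualityThreshold,
                          band = band, family = family, level = level,
                          size = size)
    log <- rbind(log, res$logRow)
    if (!is.null(res$sample)) samples[[length(samples) + 1L]] <- res$sample
  }
  list(dataset = new("LarvaDataset", samples = samples), rejections = log)
}

#' @rdname segmentCaptures
#' @param capture a single [MultispectralCapture-class].
#' @return `segmentCapture`: a list with `sample` (a
#'   [SegmentedSample-class] or NULL when rejected) and `logRow`.
#' @export
segmentCapture <- function(capture, qualityThreshold = 50, band = "GRE",
                           family = "haar", level = 1L, size = 300L) {
  stopifnot(is(capture, "MultispectralCapture"))
  wv <- waveletTransform(capture, family = family, level = level, band = band)
  g <- splitChannels(wv)$G
  score <- max(g) - median(g)
  accepted <- score >= qualityThreshold
  logRow <- data.frame(captureId = captureId(capture), score = score,
                       threshold = qualityThreshold,
                       verdict = if (accepted) "accepted" else "rejected",
                       stringsAsFactors = FALSE)
  if (!accepted) return(list(sample = NULL, logRow = logRow))
  loc <- locateLarva(g)
  crop <- cropCentered(waveletRGB(wv), loc, size = size)
  truth <- sceneTruth(capture)
  sample <- new("SegmentedSample",
                grid = crop$grid,
                label = if (is.null(truth)) NA_integer_
                        else as.integer(truth@larvaPresent),
                species = if (is.null(truth)) NA_character_
                          else truth@speciesProfile,
                cropOrigin = crop$origin,
                sourceCapture = captureId(capture),
                sampleId = paste0(captureId(capture), "-s1"),
                parentId = NA_character_, drawSeed = NA_integer_)
  list(sample = sample, logRow = logRow)
}
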