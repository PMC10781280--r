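# Separable 2-D discrete wavelet transform, approximation subband only.
# Orthonormal analysis low-pass filters; symmetric (repeat-edge) extension
# when the filter overruns, and repeat-padding of odd-length signals.
.WAVE_FILTERS <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(0.4829629131445341, 0.8365163037378079,
          0.2241438680420134, -0.1294095225512604)
)

# One analysis level along the rows of each column: y_i = sum_k h_k x[2i-1+k-1].
.dwtApproxCols <- function(x, h) {
  n <- nrow(x)
  if (n %% 2L == 1L) { x <- rbind(x, x[n, , drop = FALSE]); n <- n + 1L }
  K <- length(h)
  out <- matrix(0, n / 2L, ncol(x))
  idx0 <- seq(1L, n, by = 2L)
  for (k in seq_len(K)) {
    ii <- pmin(idx0 + k - 1L, n)  # repeat-edge extension on the right
    out <- out + h[k] * x[ii, , drop = FALSE]
  }
  out
}

.dwtApprox2D <- function(x, h) t(.dwtApproxCols(t(.dwtApproxCols(x, h)), h))

#' 2-D wavelet conversion of a band image
#'
#' Computes the approximation subband of a separable 2-D discrete wavelet
#' transform at the requested level, rescales it to 8-bit, and renders it
#' to the fixed-colormap 3-channel image used by downstream channel
#' separation (G = grid, R = B = 255 - grid, so the green channel is
#' monotone in wavelet intensity). Rescaling is linear min-max to
#' [0, 255]; a constant approximation (degenerate range) maps to the
#' constant `value / 2^level`, which undoes the orthonormal filter gain
#' and so preserves the original flat level.
#'
#' @param x a 2-D intensity grid (numeric/integer matrix), or a
#'   [MultispectralCapture-class] with `band` naming the grid to convert.
#' @param family wavelet family, `"haar"` (default) or `"db2"`.
#' @param level decomposition level, >= 1.
#' @param band band name when `x` is a capture.
#' @param ... unused.
#' @return A [WaveletImage-class].
#' @examples
#' w <- waveletTransform(matrix(runif(64, 0, 255), 8, 8))
#' dim(waveletGrid(w))
#' @export
setGeneric("waveletTransform",
           function(x, family = "haar", level = 1L, ...)
             standardGeneric("waveletTransform"))

#' @rdname waveletTransform
#' @export
setMethod("waveletTransform", "matrix",
          function(x, family = "haar", level = 1L, ..., band = NA_character_) {
  if (!family %in% names(.WAVE_FILTERS))
    stop(sprintf("unknown wavelet family '%s'; available: %s", family,
                 paste(names(.WAVE_FILTERS), collapse = ", ")))
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1")
  h <- .WAVE_FILTERS[[family]]
  a <- x
  storage.mode(a) <- "double"
  for (l in seq_len(level)) a <- .dwtApprox2D(a, h)
  rng <- range(a)
  g <- if (rng[2] > rng[1]) {
    round(255 * (a - rng[1]) / (rng[2] - rng[1]))
  } else {
    round(pmin(pmax(a / 2^level, 0), 255))
  }
  storage.mode(g) <- "integer"
  new("WaveletImage", sourceBand = band, grid = g, rgb = .renderRGB(g),
      waveletFamily = family, level = level)
})

#' @rdname waveletTransform
#' @export
setMethod("waveletTransform", "MultispectralCapture",
          function(x, family = "haar", level = 1L, ..., band = "GRE") {
  band <- match.arg(band, .BANDS)
  waveletTransform(bandImage(x, band), family = family, level = level,
                   band = band)
})

# The pipeline's colormap contract: G increases monotonically with the
# wavelet grid value so high-intensity larvae map to high G; R and B are
# its reflection.
.renderRGB <- function(grid) {
  out <- array(0L, c(dim(grid), 3L))
  out[, , 1] <- 255L - grid
  out[, , 2] <- grid
  out[, , 3] <- 255L - grid
  out
}

#' Per-column five-number summaries of a 2-D intensity grid
#'
#' The boxplot-style analysis that reveals a larva as a narrow, sharp
#' high-value column: for every image column, the minimum, lower quartile,
#' median, upper quartile, maximum and IQR of its pixel intensities.
#' Quantiles use linear interpolation (R's default type 7 rule).
#'
#' @param x a non-empty numeric/integer matrix, or a [WaveletImage-class].
#' @return A data.frame with columns `column` (1-based index), `min`, `q1`,
#'   `median`, `q3`, `max`, `iqr`; one row per image column.
#' @examples
#' columnDistribution(matrix(1:12, 3, 4))
#' @export
columnDistribution <- function(x) {
  if (is(x, "WaveletImage")) x <- waveletGrid(x)
  if (!is.matrix(x) || length(x) == 0L) stop("x must be a non-empty matrix")
  q <- apply(x, 2, quantile, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
             type = 7)
  data.frame(column = seq_len(ncol(x)), min = q[1, ], q1 = q[2, ],
             median = q[3, ], q3 = q[4, ], max = q[5, ],
             iqr = q[4, ] - q[2, ])
}

#' Band contrast scores of a capture
#'
#' Scores each band's wavelet image by how sharply a narrow high-intensity
#' feature stands out: `(max - median) / (IQR + 1)` over all pixels, where
#' the +1 intensity unit guards against division by zero on constant
#' bands. A lone bright larva drives max up while leaving median and IQR
#' at background values, so larva-bearing bands score high.
#'
#' @param capture a [MultispectralCapture-class].
#' @param family,level wavelet settings forwarded to [waveletTransform()].
#' @return A named numeric vector of scores over GRE, NIR, RED, REG.
#' @export
bandContrastScore <- function(capture, family = "haar", level = 1L) {
  stopifnot(is(capture, "MultispectralCapture"))
  vapply(setNames(.BANDS, .BANDS), function(b) {
    g <- waveletGrid(waveletTransform(capture, family = family,
                                      level = level, band = b))
    (max(g) - median(g)) / ((quantile(g, 0.75, names = FALSE) -
                             quantile(g, 0.25, names = FALSE)) + 1)
  }, numeric(1))
}

#' Select the most discriminative band over a set of captures
#'
#' Each capture votes for its highest-scoring band under
#' [bandContrastScore()]; the band with most votes wins. All ties (within
#' a capture and across vote totals) break deterministically by the fixed
#' band order GRE, NIR, RED, REG.
#'
#' @param captures non-empty list of [MultispectralCapture-class].
#' @param family,level wavelet settings.
#' @return A band name.
#' @export
selectBand <- function(captures, family = "haar", level = 1L) {
  if (length(captures) == 0L) stop("captures must be a non-empty list")
  votes <- vapply(captures, function(cp) {
    sc <- bandContrastScore(cp, family = family, level = level)
    .BANDS[which.max(sc[.BANDS])]   # which.max: first max in band order
  }, character(1))
  tab <- table(factor(votes, levels = .BANDS))
  .BANDS[which.max(tab)]
}
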