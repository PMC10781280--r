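#' Construct an AugmentationPolicy
#'
#' Defaults: rotation +/- 30 degrees, shifts +/- 10% of the side, zoom
#' factor in [0.8, 1.2], horizontal flip with probability 0.5, expansion
#' factor 4 (the original counts as one of the four).
#'
#' @param rotationRange rotation range in degrees.
#' @param shiftRange shift range as a fraction of the side.
#' @param horizontalFlip enable random horizontal flips.
#' @param zoomRange zoom range as a fraction (zoom in [1 - z, 1 + z]).
#' @param factor dataset expansion factor (>= 1).
#' @param seed integer seed for all draws.
#' @return An [AugmentationPolicy-class].
#' @examples
#' augmentationPolicy(factor = 4L, seed = 1L)
#' @export
augmentationPolicy <- function(rotationRange = 30, shiftRange = 0.1,
                               horizontalFlip = TRUE, zoomRange = 0.2,
                               factor = 4L, seed = 0L) {
  new("AugmentationPolicy", rotationRange = rotationRange,
      shiftRange = shiftRange, horizontalFlip = horizontalFlip,
      zoomRange = zoomRange, factor = as.integer(factor),
      seed = as.integer(seed))
}

# Inverse-mapped affine warp with bilinear interpolation. Source
# coordinates are clamped to the image, i.e. pixels exposed by rotation,
# shift or zoom-out are filled by nearest-edge replication (the package's
# documented fill rule). angle in degrees; shifts in px; flip mirrors
# columns; all about the image center.
.affineWarp <- function(grid, angle, shiftR, shiftC, zoom, flip) {
  d <- dim(grid)
  h <- d[1]; w <- d[2]
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  tr <- rep(seq_len(h) - 1 - cy, times = w)
  tc <- rep(seq_len(w) - 1 - cx, each = h)
  tr <- tr - shiftR
  tc <- tc - shiftC
  th <- -angle * pi / 180           # inverse rotation
  sr <- (cos(th) * tr - sin(th) * tc) / zoom
  sc <- (sin(th) * tr + cos(th) * tc) / zoom
  if (flip) sc <- -sc
  sr <- pmin(pmax(sr + cy, 0), h - 1)
  sc <- pmin(pmax(sc + cx, 0), w - 1)
  r0 <- floor(sr); c0 <- floor(sc)
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- sr - r0; fc <- sc - c0
  out <- array(0L, d)
  nch <- if (length(d) == 3L) d[3] else 1L
  for (ch in seq_len(nch)) {
    plane <- if (length(d) == 3L) grid[, , ch] else grid
    v <- (1 - fr) * (1 - fc) * plane[cbind(r0 + 1, c0 + 1)] +
         fr * (1 - fc) * plane[cbind(r1 + 1, c0 + 1)] +
         (1 - fr) * fc * plane[cbind(r0 + 1, c1 + 1)] +
         fr * fc * plane[cbind(r1 + 1, c1 + 1)]
    v <- as.integer(round(pmin(255, pmax(0, v))))
    if (length(d) == 3L) out[, , ch] <- v else out[] <- v
  }
  out
}

#' Augment one segmented sample
#'
#' Applies a random geometric transform (rotation, shift, zoom, optional
#' horizontal flip) whose parameters are drawn deterministically from
#' `drawSeed`; label, species and provenance are preserved and the lineage
#' (parent id, draw seed) recorded, so the variant is regenerable
#' bit-exactly. Exposed pixels are filled by nearest-edge replication.
#' A policy with all ranges zero and flips disabled is the identity.
#'
#' @param sample a [SegmentedSample-class].
#' @param policy an [AugmentationPolicy-class].
#' @param drawSeed integer seed for this variant's parameter draw.
#' @param variantId id for the new sample; defaults to
#'   `"<parent>-aug<drawSeed>"`.
#' @return A new [SegmentedSample-class].
#' @export
augmentImage <- function(sample, policy, drawSeed,
                         variantId = sprintf("%s-aug%d", sample@sampleId,
                                             drawSeed)) {
  stopifnot(is(sample, "SegmentedSample"), is(policy, "AugmentationPolicy"))
  side <- dim(sample@grid)[1]
  pars <- withSeed(drawSeed, list(
    angle = runif(1, -policy@rotationRange, policy@rotationRange),
    shiftR = runif(1, -policy@shiftRange, policy@shiftRange) * side,
    shiftC = runif(1, -policy@shiftRange, policy@shiftRange) * side,
    zoom = runif(1, 1 - policy@zoomRange, 1 + policy@zoomRange),
    flip = policy@horizontalFlip && runif(1) < 0.5
  ))
  identityDraw <- policy@rotationRange == 0 && policy@shiftRange == 0 &&
    policy@zoomRange == 0 && !pars$flip
  grid <- if (identityDraw) sample@grid else
    .affineWarp(sample@grid, pars$angle, pars$shiftR, pars$shiftC,
                pars$zoom, pars$flip)
  new("SegmentedSample", grid = grid, label = sample@label,
      species = sample@species, cropOrigin = sample@cropOrigin,
      sourceCapture = sample@sourceCapture, sampleId = variantId,
      parentId = sample@sampleId, drawSeed = as.integer(drawSeed))
}

#' Expand a dataset by seeded geometric augmentation
#'
#' Returns exactly `factor(policy)` times the input size: every original
#' sample followed by `factor - 1` augmented variants. Variant `j` of
#' parent `i` uses the derived draw seed
#' `(policy seed + 131071 * i + j) mod 2147483647`, recorded in the
#' variant's lineage so it can be regenerated with [augmentImage()].
#' Per-class counts scale exactly by the factor.
#'
#' @param dataset a non-empty [LarvaDataset-class].
#' @param policy an [AugmentationPolicy-class].
#' @return A [LarvaDataset-class] of length `factor * length(dataset)`.
#' @examples
#' # 169 segmented samples expand to 676 at the default factor 4
#' @export
augmentDataset <- function(dataset, policy = augmentationPolicy()) {
  stopifnot(is(dataset, "LarvaDataset"))
  if (length(dataset) == 0L) stop("dataset must be non-empty")
  out <- vector("list", policy@factor * length(dataset))
  k <- 0L
  for (i in seq_len(length(dataset))) {
    s <- dataset[[i]]
    k <- k + 1L
    out[[k]] <- s
    for (j in seq_len(policy@factor - 1L)) {
      k <- k + 1L
      ds <- deriveSeed(policy@seed, 131071 * as.double(i) + j, stride = 1)
      out[[k]] <- augmentImage(s, policy, drawSeed = ds)
    }
  }
  new("LarvaDataset", samples = out)
}
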