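#' Construct a SceneSpec
#'
#' Builds and validates a [SceneSpec-class] for the synthetic capture
#' generator. The defaults describe a typical chironomid scene: a 1200 px
#' square image, a 70 x 5 px capsule at the image center, GRE contrast 0.6
#' against 0.1 in the other bands, background level 30 and noise sd 5.
#'
#' @param imageSide image side in px.
#' @param larvaLength,larvaWidth capsule length and width in px
#'   (width < length; length + width + |curvature| must be <= 100 so the
#'   larva fits the typical < 100 x 100 observation window).
#' @param larvaOrientation orientation in degrees.
#' @param larvaCurvature perpendicular bow of the centerline in px.
#' @param larvaCenter 0-based (row, col) of the capsule center; defaults to
#'   the image center.
#' @param bandContrast named numeric over GRE/NIR/RED/REG in [0, 1]; GRE
#'   must be strictly largest.
#' @param backgroundLevel mean background intensity (8-bit).
#' @param noiseSd additive Gaussian noise sd (8-bit units).
#' @param larvaPresent logical.
#' @param speciesProfile "chironomid", "yellow_worm" or "mosquito".
#' @return A validated [SceneSpec-class].
#' @examples
#' sceneSpec(noiseSd = 0)
#' @export
sceneSpec <- function(imageSide = 1200L,
                      larvaLength = 70,
                      larvaWidth = 5,
                      larvaOrientation = 30,
                      larvaCurvature = 0,
                      larvaCenter = NULL,
                      bandContrast = c(GRE = 0.6, NIR = 0.1, RED = 0.1, REG = 0.1),
                      backgroundLevel = 30,
                      noiseSd = 5,
                      larvaPresent = TRUE,
                      speciesProfile = "chironomid") {
  if (is.null(larvaCenter)) larvaCenter <- rep((imageSide - 1) / 2, 2)
  new("SceneSpec",
      imageSide = as.integer(imageSide),
      larvaLength = larvaLength, larvaWidth = larvaWidth,
      larvaOrientation = larvaOrientation, larvaCurvature = larvaCurvature,
      larvaCenter = as.numeric(larvaCenter),
      bandContrast = bandContrast[.BANDS],
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      larvaPresent = larvaPresent, speciesProfile = speciesProfile)
}

# Fractional pixel coverage of the larva capsule, computed only inside the
# capsule's bounding box. The centerline is a (possibly bowed) segment
# sampled as a polyline; coverage ramps linearly over one pixel at the
# boundary (anti-aliasing). Returns list(rows, cols, cover) with 0-based
# row/col indices of covered pixels.
.capsuleCoverage <- function(spec) {
  L <- spec@larvaLength; W <- spec@larvaWidth
  th <- spec@larvaOrientation * pi / 180
  u <- c(cos(th), sin(th))          # along-axis unit vector (row, col space)
  v <- c(-sin(th), cos(th))         # perpendicular
  ctr <- spec@larvaCenter
  tpts <- seq(-L / 2 + W / 2, L / 2 - W / 2, length.out = max(16L, ceiling(L)))
  bow <- spec@larvaCurvature * (1 - (2 * tpts / L)^2)
  px <- ctr[1] + tpts * u[1] + bow * v[1]
  py <- ctr[2] + tpts * u[2] + bow * v[2]

  pad <- W / 2 + 1.5
  r0 <- max(0, floor(min(px) - pad)); r1 <- min(spec@imageSide - 1, ceiling(max(px) + pad))
  c0 <- max(0, floor(min(py) - pad)); c1 <- min(spec@imageSide - 1, ceiling(max(py) + pad))
  rows <- r0:r1; cols <- c0:c1
  gr <- rep(rows, times = length(cols))
  gc <- rep(cols, each = length(rows))

  # distance from each pixel center to the polyline (minimum over segments)
  d2 <- rep(Inf, length(gr))
  for (s in seq_len(length(tpts) - 1L)) {
    ax <- px[s]; ay <- py[s]
    bx <- px[s + 1L]; by <- py[s + 1L]
    abx <- bx - ax; aby <- by - ay
    ab2 <- abx^2 + aby^2
    t <- if (ab2 > 0) pmin(1, pmax(0, ((gr - ax) * abx + (gc - ay) * aby) / ab2)) else 0
    dx <- gr - (ax + t * abx); dy <- gc - (ay + t * aby)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  cover <- pmin(1, pmax(0, W / 2 + 0.5 - sqrt(d2)))
  keep <- cover > 0
  list(rows = gr[keep], cols = gc[keep], cover = cover[keep])
}

#' Ground-truth larva mask of a synthetic scene
#'
#' Recomputes, deterministically from the [SceneSpec-class], the logical
#' mask of pixels more than half covered by the larva capsule.
#'
#' @param spec a [SceneSpec-class] (or a capture's [sceneTruth()]).
#' @return A logical matrix of dimension imageSide x imageSide; all-FALSE
#'   when the scene has no larva.
#' @export
larvaMask <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  m <- matrix(FALSE, spec@imageSide, spec@imageSide)
  if (!spec@larvaPresent) return(m)
  cov <- .capsuleCoverage(spec)
  sel <- cov$cover > 0.5
  m[cbind(cov$rows[sel] + 1L, cov$cols[sel] + 1L)] <- TRUE
  m
}

#' Generate one synthetic multispectral capture
#'
#' Renders the scene described by `spec` into four co-registered 8-bit band
#' grids: a flat background at `backgroundLevel`, plus (when the larva is
#' present) an anti-aliased capsule lifted by `bandContrast[band] * 255`,
#' plus additive Gaussian conversion noise of sd `noiseSd`, clipped to
#' [0, 255] and rounded. Identical (spec, seed) pairs produce bit-identical
#' captures.
#'
#' @param spec a [SceneSpec-class].
#' @param seed non-negative integer seeding the noise draw.
#' @param captureId identifier; defaults to `"cap-<seed>"`.
#' @return A [MultispectralCapture-class] carrying `spec` as its truth.
#' @examples
#' cap <- generateCapture(sceneSpec(imageSide = 256L, larvaCenter = c(128, 128)), seed = 1)
#' cap
#' @export
generateCapture <- function(spec, seed, captureId = sprintf("cap-%d", seed)) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  if (seed < 0) stop("seed must be a non-negative integer")
  side <- spec@imageSide

  cov <- NULL
  if (spec@larvaPresent) {
    cov <- .capsuleCoverage(spec)
    half <- (spec@larvaLength + spec@larvaWidth + abs(spec@larvaCurvature)) / 2
    if (any(spec@larvaCenter - half < -0.5) ||
        any(spec@larvaCenter + half > side - 0.5))
      stop(sprintf(
        "larva bounding box extends outside the %d x %d image (center %.0f, %.0f)",
        side, side, spec@larvaCenter[1], spec@larvaCenter[2]))
  }

  bands <- withSeed(seed, {
    lapply(setNames(.BANDS, .BANDS), function(b) {
      g <- matrix(spec@backgroundLevel, side, side)
      if (!is.null(cov)) {
        lift <- spec@bandContrast[[b]] * 255
        idx <- cbind(cov$rows + 1L, cov$cols + 1L)
        g[idx] <- g[idx] + lift * cov$cover
      }
      if (spec@noiseSd > 0)
        g <- g + matrix(rnorm(side * side, sd = spec@noiseSd), side, side)
      mode(g) <- "numeric"
      matrix(as.integer(round(pmin(255, pmax(0, g)))), side, side)
    })
  })

  new("MultispectralCapture", bands = bands, truth = spec,
      captureId = captureId)
}

# Species-specific geometry ranges (px) for randomized scenes. Chironomid
# larvae are the longest and thinnest; yellow worms shorter and stouter;
# mosquito larvae the smallest. Free parameters of the generator, recorded
# here as the single source of truth.
.SPECIES_RANGES <- list(
  chironomid  = list(length = c(55, 85), width = c(4, 8),  curvature = c(0, 6)),
  yellow_worm = list(length = c(40, 70), width = c(8, 14), curvature = c(0, 5)),
  mosquito    = list(length = c(30, 55), width = c(5, 10), curvature = c(0, 4))
)

#' Draw a randomized SceneSpec for a species
#'
#' Samples larva geometry (length, width, curvature from species-specific
#' ranges; orientation uniform over 0-180 degrees; center uniform inside a
#' margin keeping the capsule in frame), background level uniform in
#' [25, 35] and per-band contrasts (GRE uniform in [0.5, 0.7], others in
#' [0.05, 0.2]) from the given seed.
#'
#' @param species species profile.
#' @param seed integer seed.
#' @param imageSide image side in px.
#' @param larvaPresent logical.
#' @param noiseSd noise sd passed through to the spec.
#' @return A [SceneSpec-class].
#' @export
drawSceneSpec <- function(species = "chironomid", seed = 0L,
                          imageSide = 1200L, larvaPresent = TRUE,
                          noiseSd = 5) {
  species <- match.arg(species, .SPECIES)
  rng <- .SPECIES_RANGES[[species]]
  withSeed(seed, {
    len <- runif(1, rng$length[1], rng$length[2])
    wid <- runif(1, rng$width[1], rng$width[2])
    curv <- runif(1, rng$curvature[1], rng$curvature[2])
    margin <- (len + wid + curv) / 2 + 1
    ctr <- runif(2, margin, imageSide - 1 - margin)
    contrast <- c(GRE = runif(1, 0.5, 0.7),
                  NIR = runif(1, 0.05, 0.2),
                  RED = runif(1, 0.05, 0.2),
                  REG = runif(1, 0.05, 0.2))
    sceneSpec(imageSide = imageSide, larvaLength = len, larvaWidth = wid,
              larvaOrientation = runif(1, 0, 180), larvaCurvature = curv,
              larvaCenter = ctr, bandContrast = contrast,
              backgroundLevel = runif(1, 25, 35), noiseSd = noiseSd,
              larvaPresent = larvaPresent, speciesProfile = species)
  })
}

#' Derived per-capture seed
#'
#' The documented mixing rule `(master + 1000003 * index) mod 2147483647`
#' mapping a master seed and a 1-based capture index to the seed that
#' regenerates that capture bit-exactly.
#'
#' @param master master seed.
#' @param index 1-based capture index.
#' @return An integer seed.
#' @export
captureSeed <- function(master, index) deriveSeed(master, index)

#' Generate a seeded dataset of multispectral captures
#'
#' Produces `nPresent` larva-present scenes followed by `nAbsent` empty
#' scenes, with geometry randomized per capture from the species profile.
#' Capture `i` uses the derived seed [captureSeed()](seed, i) for both its
#' geometry draw and its noise, so any capture is individually regenerable
#' as `generateCapture(drawSceneSpec(species, captureSeed(seed, i), ...),
#' captureSeed(seed, i))`.
#'
#' @param nPresent,nAbsent non-negative capture counts.
#' @param species species profile for present scenes.
#' @param seed master seed.
#' @param imageSide image side in px.
#' @param noiseSd noise sd for all captures.
#' @return A list of [MultispectralCapture-class], length
#'   `nPresent + nAbsent`. For large datasets prefer streaming captures one
#'   at a time from [captureSeed()] and [generateCapture()]; a 1200 px
#'   capture holds four 1.4-megapixel grids.
#' @examples
#' caps <- generateDataset(2, 1, seed = 7, imageSide = 256L)
#' length(caps)
#' @export
generateDataset <- function(nPresent, nAbsent, species = "chironomid",
                            seed = 0L, imageSide = 1200L, noiseSd = 5) {
  stopifnot(nPresent >= 0, nAbsent >= 0)
  n <- nPresent + nAbsent
  lapply(seq_len(n), function(i) {
    present <- i <= nPresent
    s <- captureSeed(seed, i)
    spec <- drawSceneSpec(species, seed = s, imageSide = imageSide,
                          larvaPresent = present, noiseSd = noiseSd)
    generateCapture(spec, seed = s,
                    captureId = sprintf("%s-%s-%04d", species,
                                        if (present) "pos" else "neg", i))
  })
}
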