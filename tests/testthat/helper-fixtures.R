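# Fixtures are built in code at test time; nothing is stored on disk.

# A 300x300x3 sample with reproducible random content.
makeTestSample <- function(seed = 1L, label = 1L, species = "chironomid") {
  grid <- larvaDetect:::withSeed(seed, {
    array(sample.int(256L, 300L * 300L * 3L, replace = TRUE) - 1L,
          c(300L, 300L, 3L))
  })
  new("SegmentedSample", grid = grid, label = as.integer(label),
      species = species, cropOrigin = c(0L, 0L), sourceCapture = "fixture",
      sampleId = sprintf("fix-%d-%d", seed, label),
      parentId = NA_character_, drawSeed = NA_integer_)
}

makeTestDataset <- function(n, labels = rep(1L, n)) {
  new("LarvaDataset",
      samples = lapply(seq_len(n), function(i) makeTestSample(i, labels[i])))
}

# A capture built directly from band matrices (no truth).
makeBandCapture <- function(bands, id = "cap-fixture") {
  new("MultispectralCapture", bands = bands[c("GRE", "NIR", "RED", "REG")],
      truth = NULL, captureId = id)
}

# Constant-background capture with a square bright spike in chosen bands.
# With noiseSd > 0 the per-band rescale leaves a noise floor, so the
# contrast score reflects each band's true spike amplitude; noiseless
# spikes all stretch to the full range and tie.
makeSpikeCapture <- function(spikeLift = c(GRE = 150, NIR = 25, RED = 25,
                                           REG = 25),
                             side = 64L, background = 30L, noiseSd = 0,
                             id = "spike", seed = 99L) {
  bands <- larvaDetect:::withSeed(seed, lapply(spikeLift, function(lift) {
    m <- matrix(background, side, side)
    m[20:25, 30:35] <- background + lift
    if (noiseSd > 0) m <- m + matrix(rnorm(side^2, sd = noiseSd), side, side)
    matrix(as.integer(round(pmin(pmax(m, 0), 255))), side, side)
  }))
  makeBandCapture(bands, id = id)
}

# Linearly separable toy tensors: two constant-image classes.
toyTensors <- function(n = 20L, side = 12L) {
  x <- array(0L, c(side, side, 3L, n))
  half <- n %/% 2L
  x[, , , seq_len(half)] <- 50L
  x[, , , (half + 1L):n] <- 200L
  list(x = x, y = c(rep(0, half), rep(1, n - half)))
}

toyArch <- function(side = 12L) {
  cnnArchitecture(inputSide = side, convFilters = c(4L, 8L),
                  denseUnits = 16L)
}

# Independent type-7 quantile: sort-based linear interpolation.
oracleQuantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, length(x))
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
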