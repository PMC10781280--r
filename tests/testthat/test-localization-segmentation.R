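test_that("channel separation is lossless and shape-checked", {
  img <- array(0L, c(4, 6, 3))
  img[, , 1] <- 10L; img[, , 2] <- 200L; img[, , 3] <- 30L
  pl <- splitChannels(img)
  expect_true(all(pl$G == 200L))
  restacked <- array(0L, dim(img))
  restacked[, , 1] <- pl$R; restacked[, , 2] <- pl$G; restacked[, , 3] <- pl$B
  expect_identical(restacked, img)
  expect_error(splitChannels(array(0, c(4, 4, 2))), "3-channel")
})

test_that("the G plane peaks at the larva for a rendered present scene", {
  sp <- drawSceneSpec("chironomid", seed = 8, imageSide = 256L, noiseSd = 5)
  cap <- generateCapture(sp, seed = 8)
  w <- waveletTransform(cap, band = "GRE")
  g <- splitChannels(w)$G
  mask <- larvaMask(sp)
  cent <- round(colMeans(which(mask, arr.ind = TRUE)) / 2)  # wavelet scale
  expect_gt(g[cent[1], cent[2]], median(g))
})

test_that("locateLarva returns the 0-based global maximum with row-major tie-break", {
  m <- matrix(0L, 500, 500); m[413, 88] <- 255L
  expect_identical(unname(locateLarva(m)), c(412L, 87L))
  expect_identical(unname(locateLarva(matrix(3, 5, 5))), c(0L, 0L))
  m <- matrix(0L, 10, 10); m[7, 2] <- 9L; m[3, 8] <- 9L; m[3, 4] <- 9L
  expect_identical(unname(locateLarva(m)), c(2L, 3L))  # min row, then min col
  expect_error(locateLarva(matrix(0, 0, 0)), "non-empty")
})

test_that("centered crops are exact, clamped at borders, never padded", {
  img <- matrix(0, 1200, 1200)
  expect_identical(cropCentered(img, c(600, 600))$origin, c(450L, 450L))
  expect_identical(cropCentered(img, c(10, 10))$origin, c(0L, 0L))
  expect_identical(cropCentered(img, c(1195, 600))$origin, c(900L, 450L))
  for (ctr in list(c(600, 600), c(0, 0), c(1199, 1199), c(3, 1100))) {
    cr <- cropCentered(img, ctr)
    expect_identical(dim(cr$grid), c(300L, 300L))
    expect_true(all(cr$origin >= 0L) && all(cr$origin + 300L <= 1200L))
  }
  expect_error(cropCentered(matrix(0, 100, 100), c(50, 50)), "smaller")
})

test_that("segmentation accepts feature-bearing captures and logs rejections", {
  clean <- generateDataset(5, 0, "chironomid", seed = 19, imageSide = 640L,
                           noiseSd = 0)
  res <- segmentCaptures(clean, qualityThreshold = 50)
  expect_length(res$dataset@samples, 5)
  expect_true(all(res$rejections$verdict == "accepted"))

  flatBands <- lapply(setNames(rep(30L, 4), c("GRE", "NIR", "RED", "REG")),
                      function(v) matrix(v, 640, 640))
  flats <- lapply(1:5, function(i) makeBandCapture(flatBands,
                                                   id = sprintf("flat-%d", i)))
  res <- segmentCaptures(flats, qualityThreshold = 50)
  expect_length(res$dataset@samples, 0)
  expect_true(all(res$rejections$verdict == "rejected"))

  mixed <- c(generateDataset(8, 0, "chironomid", seed = 23,
                             imageSide = 640L), flats[1:3])
  res <- segmentCaptures(mixed, qualityThreshold = 50)
  expect_length(res$dataset@samples, 8)
  expect_identical(sum(res$rejections$verdict == "rejected"), 3L)

  info <- sampleInfo(res$dataset)
  expect_true(all(info$label == 1L))
})

test_that("every emitted sample is a 300x300x3 in-bounds crop", {
  caps <- generateDataset(4, 2, "yellow_worm", seed = 29, imageSide = 640L)
  res <- segmentCaptures(caps)
  for (s in res$dataset@samples) {
    expect_identical(dim(s@grid), c(300L, 300L, 3L))
    expect_true(all(s@cropOrigin >= 0L))
    expect_true(all(s@cropOrigin + 300L <= 320L))  # wavelet side = 640 / 2
  }
})

test_that("clean-scene localization lands exactly on a brightest larva pixel", {
  for (seed in c(3, 14, 15)) {
    sp <- drawSceneSpec("chironomid", seed = seed, imageSide = 256L,
                        noiseSd = 0)
    cap <- generateCapture(sp, seed = seed)
    g <- bandImage(cap, "GRE")
    loc <- locateLarva(g)
    expect_identical(g[loc[1] + 1L, loc[2] + 1L], max(g))
    expect_true(larvaMask(sp)[loc[1] + 1L, loc[2] + 1L])
  }
})

test_that("localization recovers the planted larva in >= 95 of 100 noisy scenes", {
  hits <- 0L
  for (i in 1:100) {
    s <- captureSeed(314, i)
    sp <- drawSceneSpec("chironomid", seed = s, imageSide = 256L,
                        noiseSd = 10)
    cap <- generateCapture(sp, seed = s)
    g <- splitChannels(waveletTransform(cap, band = "GRE"))$G
    loc <- locateLarva(g)
    srcPt <- 2 * loc + 0.5                       # wavelet -> source px
    maskPx <- which(larvaMask(sp), arr.ind = TRUE) - 1L
    d <- sqrt(min((maskPx[, 1] - srcPt[1])^2 + (maskPx[, 2] - srcPt[2])^2))
    if (d <= 5) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("acceptance rate is monotone non-increasing in the quality threshold", {
  caps <- c(generateDataset(6, 3, "chironomid", seed = 41, imageSide = 640L,
                            noiseSd = 2),
            list(makeBandCapture(lapply(
              setNames(rep(30L, 4), c("GRE", "NIR", "RED", "REG")),
              function(v) matrix(v, 640, 640)), id = "flat")))
  accepted <- vapply(c(0, 50, 120, 254, 300), function(th) {
    length(segmentCaptures(caps, qualityThreshold = th)$dataset@samples)
  }, integer(1))
  expect_true(all(diff(accepted) <= 0))
  expect_identical(accepted[1], 10L)   # everything passes at threshold 0
  expect_identical(accepted[5], 0L)    # nothing can exceed max - median > 255
})
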