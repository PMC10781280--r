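test_that("constant grids stay constant through the wavelet transform", {
  for (fam in c("haar", "db2")) {
    w <- waveletTransform(matrix(30, 8, 8), family = fam)
    expect_true(all(waveletGrid(w) == 30L), info = fam)
  }
})

test_that("level-1 haar approximation matches 2x2 block means up to rescale", {
  set.seed(4)
  m <- matrix(sample(0:255, 36), 6, 6)
  bm <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    bm[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expected <- round(255 * (bm - min(bm)) / (max(bm) - min(bm)))
  w <- waveletTransform(m, family = "haar", level = 1L)
  expect_equal(waveletGrid(w), matrix(as.integer(expected), 3, 3))
})

test_that("unknown families and invalid levels are configuration errors", {
  expect_error(waveletTransform(matrix(0, 4, 4), family = "sym9"), "unknown")
  expect_error(waveletTransform(matrix(0, 4, 4), level = 0L), "level")
})

test_that("odd dimensions are padded, never dropped", {
  w <- waveletTransform(matrix(runif(35, 0, 255), 5, 7))
  expect_identical(dim(waveletGrid(w)), c(3L, 4L))
})

test_that("output range and colormap contract hold on random grids", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(runif(64 * 64, -50, 400), 64, 64)  # deliberately out of range
    w <- waveletTransform(m, family = sample(c("haar", "db2"), 1))
    g <- waveletGrid(w)
    expect_gte(min(g), 0); expect_lte(max(g), 255)
    rgb <- waveletRGB(w)
    expect_identical(rgb[, , 2], g)                 # G monotone in grid
    expect_identical(rgb[, , 1], 255L - g)
    expect_identical(rgb[, , 3], 255L - g)
  }
})

test_that("a planted larva's column span survives the wavelet transform", {
  sp <- drawSceneSpec("chironomid", seed = 5, imageSide = 256L, noiseSd = 0)
  cap <- generateCapture(sp, seed = 5)
  w <- waveletTransform(cap, band = "GRE")
  mask <- larvaMask(sp)
  span <- range(which(colSums(mask) > 0))           # source columns, 1-based
  g <- waveletGrid(w)
  maxCol <- arrayInd(which.max(g), dim(g))[2]       # wavelet column
  expect_gte(maxCol, floor((span[1] - 1) / 2))
  expect_lte(maxCol, ceiling(span[2] / 2) + 1)
})

test_that("per-column summaries behave on degenerate grids", {
  cs <- columnDistribution(matrix(7, 5, 4))
  expect_true(all(cs$min == 7 & cs$q1 == 7 & cs$median == 7 &
                  cs$q3 == 7 & cs$max == 7))
  m <- matrix(0, 10, 6); m[, 3] <- 255
  cs <- columnDistribution(m)
  expect_identical(cs$max, c(0, 0, 255, 0, 0, 0))
  expect_error(columnDistribution(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("per-column summaries match a sort-based quantile oracle", {
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(runif(50 * 50, 0, 255), 50, 50)
    cs <- columnDistribution(m)
    for (j in sample(50, 8)) {
      expect_equal(cs$q1[j], oracleQuantile(m[, j], 0.25))
      expect_equal(cs$median[j], oracleQuantile(m[, j], 0.5))
      expect_equal(cs$q3[j], oracleQuantile(m[, j], 0.75))
      expect_equal(cs$min[j], min(m[, j]))
      expect_equal(cs$max[j], max(m[, j]))
    }
  }
})

test_that("columns crossing the larva hold the global maximum whisker", {
  sp <- drawSceneSpec("chironomid", seed = 31, imageSide = 256L, noiseSd = 5)
  cap <- generateCapture(sp, seed = 31)
  g <- waveletGrid(waveletTransform(cap, band = "GRE"))
  cs <- columnDistribution(g)
  mask <- larvaMask(sp)
  larvaCols <- unique(ceiling(which(colSums(mask) > 0) / 2))  # wavelet scale
  expect_true(which.max(cs$max) %in% larvaCols)
})

test_that("band contrast scores separate feature-bearing bands", {
  flat <- makeBandCapture(lapply(
    setNames(rep(30L, 4), c("GRE", "NIR", "RED", "REG")),
    function(v) matrix(v, 32, 32)))
  expect_true(all(bandContrastScore(flat) == 0))

  spike <- makeSpikeCapture(noiseSd = 5)
  sc <- bandContrastScore(spike)
  expect_identical(names(which.max(sc)), "GRE")

  twin <- makeSpikeCapture(spikeLift = c(GRE = 150, NIR = 150, RED = 25,
                                         REG = 25))
  sc <- bandContrastScore(twin)
  expect_equal(sc[["GRE"]], sc[["NIR"]])            # function of grid only
})

test_that("band selection is data-driven with a deterministic tie-break", {
  caps <- generateDataset(10, 0, "chironomid", seed = 13, imageSide = 128L)
  expect_identical(selectBand(caps), "GRE")

  flat <- makeBandCapture(lapply(
    setNames(rep(30L, 4), c("GRE", "NIR", "RED", "REG")),
    function(v) matrix(v, 32, 32)))
  expect_identical(selectBand(list(flat)), "GRE")   # tie-break by band order

  nirCaps <- lapply(1:5, function(i)
    makeSpikeCapture(spikeLift = c(GRE = 30, NIR = 160, RED = 20, REG = 20),
                     noiseSd = 5, id = sprintf("nir-%d", i), seed = i))
  expect_identical(selectBand(nirCaps), "NIR")

  expect_error(selectBand(list()), "non-empty")
})
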