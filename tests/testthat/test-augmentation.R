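test_that("an all-zero-range policy is the identity", {
  s <- makeTestSample(1)
  pol <- augmentationPolicy(rotationRange = 0, shiftRange = 0,
                            horizontalFlip = FALSE, zoomRange = 0)
  out <- augmentImage(s, pol, drawSeed = 99L)
  expect_identical(out@grid, s@grid)
  expect_identical(out@label, s@label)
  expect_identical(out@parentId, s@sampleId)
})

test_that("augmentation draws are deterministic in the draw seed", {
  s <- makeTestSample(2)
  pol <- augmentationPolicy(seed = 5L)
  a <- augmentImage(s, pol, drawSeed = 123L)
  b <- augmentImage(s, pol, drawSeed = 123L)
  expect_identical(a@grid, b@grid)
  c <- augmentImage(s, pol, drawSeed = 124L)
  expect_false(identical(a@grid, c@grid))
})

test_that("a horizontal flip is an involution", {
  s <- makeTestSample(3)
  pol <- augmentationPolicy(rotationRange = 0, shiftRange = 0,
                            horizontalFlip = TRUE, zoomRange = 0)
  # find a draw seed whose flip coin lands on "flip"
  flipSeed <- NULL
  for (ds in 1:50) {
    flips <- larvaDetect:::withSeed(ds, { runif(4); runif(1) < 0.5 })
    if (flips) { flipSeed <- ds; break }
  }
  expect_false(is.null(flipSeed))
  once <- augmentImage(s, pol, drawSeed = flipSeed)
  expect_false(identical(once@grid, s@grid))
  twice <- augmentImage(once, pol, drawSeed = flipSeed)
  expect_identical(twice@grid, s@grid)
})

test_that("labels, species and pixel range are preserved under warping", {
  s <- makeTestSample(4, label = 0L, species = "mosquito")
  out <- augmentImage(s, augmentationPolicy(), drawSeed = 7L)
  expect_identical(dim(out@grid), c(300L, 300L, 3L))
  expect_identical(out@label, 0L)
  expect_identical(out@species, "mosquito")
  expect_gte(min(out@grid), 0L); expect_lte(max(out@grid), 255L)
})

test_that("dataset expansion is exactly factor x input for any size", {
  for (n in c(1L, 3L, 7L)) {
    for (f in c(1L, 2L, 4L)) {
      ds <- makeTestDataset(n, labels = rep_len(c(1L, 0L), n))
      out <- augmentDataset(ds, augmentationPolicy(factor = f, seed = 2L))
      expect_length(out@samples, f * n)
      # per-class counts scale exactly by the factor
      expect_identical(table(datasetLabels(out)),
                       table(rep(datasetLabels(ds), f)))
    }
  }
  expect_error(augmentDataset(new("LarvaDataset", samples = list())),
               "non-empty")
})

test_that("factor 1 returns only the originals", {
  ds <- makeTestDataset(2)
  out <- augmentDataset(ds, augmentationPolicy(factor = 1L))
  expect_identical(lapply(out@samples, slot, "grid"),
                   lapply(ds@samples, slot, "grid"))
})

test_that("every variant regenerates bit-exactly from its recorded lineage", {
  ds <- makeTestDataset(3)
  pol <- augmentationPolicy(factor = 3L, seed = 17L)
  out <- augmentDataset(ds, pol)
  info <- sampleInfo(out)
  variants <- which(!is.na(info$parentId))
  expect_length(variants, 6)
  byId <- setNames(out@samples, info$sampleId)
  for (k in variants) {
    parent <- byId[[info$parentId[k]]]
    regen <- augmentImage(parent, pol, drawSeed = info$drawSeed[k])
    expect_identical(regen@grid, out@samples[[k]]@grid)
  }
})
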