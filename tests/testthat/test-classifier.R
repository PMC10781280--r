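test_that("the default architecture reproduces the canonical shape chain", {
  sh <- computeLayerShapes(cnnArchitecture())
  expect_identical(sh$side[1:6], c(298L, 149L, 147L, 73L, 71L, 35L))
  expect_identical(flattenLength(cnnArchitecture()), 78400L)
  expect_identical(layerCount(cnnArchitecture()), 10L)
})

test_that("shape arithmetic matches a hand-computed oracle on a tiny spec", {
  a <- cnnArchitecture(inputSide = 6L, convFilters = 1L, denseUnits = 4L)
  sh <- computeLayerShapes(a)
  expect_identical(sh$side[1:2], c(4L, 2L))
  expect_identical(flattenLength(a), 4L)
})

test_that("impossible chains raise spec errors", {
  expect_error(computeLayerShapes(
    cnnArchitecture(inputSide = 8L, convFilters = c(4L, 8L, 16L))),
    "non-positive")
})

test_that("the residual backbone walk matches the ceil-mode chain", {
  expect_identical(resnetHeadFlattenSize(300), 204800L)
  expect_identical(resnetHeadFlattenSize(32), 2048L)
  expect_identical(resnetHeadFlattenSize(64), 8192L)
  expect_identical(resnetLayerCount(), 101L)
  # independent oracle: five successive ceil(s / 2) halvings, 2048 channels
  ceilChain <- function(s) { for (i in 1:5) s <- ceiling(s / 2); s }
  for (side in c(32, 64, 128, 224, 300, 513)) {
    sh <- resnetHeadShapes(side)
    expect_identical(sh$side[nrow(sh)], as.integer(ceilChain(side)))
    expect_identical(resnetHeadFlattenSize(side),
                     as.integer(ceilChain(side)^2 * 2048))
  }
  expect_error(resnetHeadShapes(31), ">= 32")
})

test_that("built models report the same shapes as the analytic chain", {
  set.seed(42)
  for (i in 1:20) {
    nb <- sample(1:3, 1)
    arch <- cnnArchitecture(inputSide = sample(30:40, 1),
                            convFilters = sample(1:8, nb, replace = TRUE),
                            denseUnits = sample(8:64, 1))
    m <- buildCNN(arch, seed = i)
    expect_identical(modelLayerShapes(m)[c("layer", "side", "units")],
                     computeLayerShapes(arch)[c("layer", "side", "units")])
  }
})

test_that("the built default model has 10 layers, flatten 78400 and echoes dense width", {
  m <- buildCNN(cnnArchitecture())
  sh <- modelLayerShapes(m)
  expect_identical(nrow(sh), 10L)
  expect_identical(sh$units[sh$layer == "flatten"], 78400L)
  m512 <- buildCNN(cnnArchitecture(denseUnits = 512L))
  sh <- modelLayerShapes(m512)
  expect_identical(sh$units[9], 512L)   # dropout row width
})

test_that("splits are exact, disjoint, exhaustive and deterministic", {
  idx <- splitIndices(rep(0:1, 5), ratio = 0.7, seed = 1,
                      stratified = FALSE)
  expect_length(idx$train, 7)
  expect_length(idx$test, 3)
  expect_identical(splitIndices(rep(0:1, 5), 0.7, seed = 9),
                   splitIndices(rep(0:1, 5), 0.7, seed = 9))

  set.seed(6)
  for (n in c(2:40, sample(41:1000, 15))) {
    labels <- sample(0:1, n, replace = TRUE)
    strat <- all(table(factor(labels, levels = 0:1)) >= 2)
    for (ratio in c(0.5, 0.7)) {
      idx <- splitIndices(labels, ratio, seed = n, stratified = strat)
      expect_length(idx$train, floor(ratio * n))
      expect_identical(sort(c(idx$train, idx$test)), seq_len(n))
    }
  }
})

test_that("stratified splits keep class skew at most one", {
  labels <- rep(0:1, each = 338)
  idx <- splitIndices(labels, 0.7, seed = 3, stratified = TRUE)
  expect_length(idx$train, 473)
  tab <- table(labels[idx$train])
  expect_lte(abs(tab[[1]] - tab[[2]]), 1)
  expect_error(splitIndices(c(0, 1, 1, 1), stratified = TRUE),
               "at least 2")
})

test_that("lineage-aware splits never separate augmentation siblings", {
  ds <- augmentDataset(makeTestDataset(6, labels = rep(0:1, 3)),
                       augmentationPolicy(factor = 3L, seed = 1L))
  idx <- splitIndices(ds, ratio = 0.7, seed = 2, lineageAware = TRUE)
  info <- sampleInfo(ds)
  root <- ifelse(is.na(info$parentId), info$sampleId, info$parentId)
  side <- ifelse(seq_along(root) %in% idx$train, "train", "test")
  expect_true(all(tapply(side, root, function(x) length(unique(x))) == 1))
})

test_that("training separates a linearly separable toy problem", {
  toy <- toyTensors()
  cfg <- trainingConfig(epochs = 40L, learningRate = 1e-2, batchSize = 4L,
                        seed = 1L)
  m <- trainCNN(toy$x, toy$y, arch = toyArch(), config = cfg,
                validation = list(x = toy$x, y = toy$y))
  h <- modelHistory(m)
  expect_identical(nrow(h), 40L)
  expect_equal(h$train_acc[40], 1.0)
  expect_equal(h$val_acc[40], 1.0)
  expect_lt(h$train_loss[40], 0.1)
  expect_equal(mean((predict(m, toy$x) >= 0.5) == (toy$y == 1)), 1.0)
})

test_that("training runs repeat bit-identically for a fixed seed", {
  toy <- toyTensors()
  cfg <- trainingConfig(epochs = 10L, learningRate = 1e-2, batchSize = 4L,
                        seed = 7L)
  m1 <- trainCNN(toy$x, toy$y, arch = toyArch(), config = cfg)
  m2 <- trainCNN(toy$x, toy$y, arch = toyArch(), config = cfg)
  expect_identical(m1@history$train_loss, m2@history$train_loss)
  expect_identical(predict(m1, toy$x), predict(m2, toy$x))
})

test_that("an excessive learning rate is flagged unstable, a moderate one stable", {
  toy <- toyTensors()
  stable <- trainCNN(toy$x, toy$y, arch = toyArch(),
                     config = trainingConfig(epochs = 40L,
                                             learningRate = 1e-2,
                                             batchSize = 4L, seed = 1L))
  expect_identical(trainingStability(stable), "stable")
  hot <- trainCNN(toy$x, toy$y, arch = toyArch(),
                  config = trainingConfig(epochs = 40L, learningRate = 0.1,
                                          batchSize = 4L, seed = 1L))
  expect_identical(trainingStability(hot), "unstable")
})

test_that("SGD and RMSprop optimizers run and learn the toy problem", {
  toy <- toyTensors()
  rates <- c(SGD = 1e-2, RMSprop = 1e-3)  # RMSprop steps ~1/sqrt(v) larger
  for (opt in names(rates)) {
    m <- trainCNN(toy$x, toy$y, arch = toyArch(),
                  config = trainingConfig(epochs = 40L,
                                          learningRate = rates[[opt]],
                                          optimizer = opt, batchSize = 4L,
                                          seed = 2L))
    expect_false(m@diverged)
    expect_equal(mean((predict(m, toy$x) >= 0.5) == (toy$y == 1)), 1.0,
                 info = opt)
  }
})

test_that("the hyperparameter grid yields one ranked record per combination", {
  toy <- toyTensors()
  gs <- gridSearch(toy$x, toy$y, validation = list(x = toy$x, y = toy$y),
                   epochsGrid = c(4L, 8L), lrGrid = c(1e-3, 1e-2),
                   arch = toyArch(),
                   baseConfig = trainingConfig(batchSize = 4L, seed = 3L))
  expect_identical(nrow(gs$results), 4L)
  expect_setequal(gs$results$rank, 1:4)
  # ranking is reproducible from the persisted metrics
  r <- gs$results
  ord <- order(r$diverged, -r$val_acc, r$val_loss)
  expect_identical(r$rank[ord], 1:4)
  expect_identical(gs$best, which(r$rank == 1L))
  # ties on accuracy resolve by validation loss
  top <- r[r$rank <= 2, ]
  if (top$val_acc[1] == top$val_acc[2])
    expect_lte(r$val_loss[r$rank == 1], r$val_loss[r$rank == 2])
})
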