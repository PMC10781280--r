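test_that("probability RMSE matches closed forms and a brute-force oracle", {
  expect_identical(probabilityRMSE(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_identical(probabilityRMSE(c(0.5, 0.5), c(0, 1)), 0.5)
  expect_equal(probabilityRMSE(c(0.9, 0.2, 0.8), c(1, 0, 1)),
               sqrt((0.01 + 0.04 + 0.04) / 3), tolerance = 1e-12)
  expect_error(probabilityRMSE(c(0.5), c(0, 1)), "equal length")
  expect_error(probabilityRMSE(numeric(0), numeric(0)), "non-empty")

  set.seed(10)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    p <- runif(n); y <- sample(0:1, n, replace = TRUE)
    acc <- 0
    for (j in seq_len(n)) acc <- acc + (p[j] - y[j])^2
    expect_equal(probabilityRMSE(p, y), sqrt(acc / n), tolerance = 1e-12)
  }
})

test_that("confusion-derived metrics match hand-computed tables", {
  r <- classificationMetrics(c(0.9, 0.1), c(1, 0))
  expect_equal(r@accuracy, 1.0)
  expect_equal(r@f1, 1.0)
  expect_identical(as.vector(r@confusion), c(1L, 0L, 0L, 1L))

  r <- classificationMetrics(c(0.9, 0.9), c(1, 0))
  expect_equal(r@accuracy, 0.5)
  expect_equal(r@precision, 0.5)
  expect_equal(r@recall, 1.0)
  expect_equal(r@f1, 2 / 3)

  expect_warning(r <- classificationMetrics(c(0.1, 0.2), c(0, 0)),
                 "reporting 0")
  expect_equal(r@accuracy, 1.0)
  expect_equal(r@precision, 0)
})

test_that("accuracy always equals its own confusion recomputation", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:100, 1)
    p <- runif(n); y <- sample(0:1, n, replace = TRUE)
    r <- suppressWarnings(classificationMetrics(p, y, threshold = runif(1)))
    expect_identical(sum(r@confusion), r@nEval)
    expect_equal(r@accuracy, (r@confusion[1, 1] + r@confusion[2, 2]) / n)
  }
})

test_that("the real-time rule picks the faster model among perfect ones", {
  cnn <- new("EvalReport", modelId = "cnn", accuracy = 1, precision = 1,
             recall = 1, f1 = 1,
             confusion = matrix(c(51L, 0L, 0L, 51L), 2), rmse = 3.16e-5,
             trainingSeconds = 883, nEval = 102L)
  resnet <- new("EvalReport", modelId = "resnet101", accuracy = 1,
                precision = 1, recall = 1, f1 = 1,
                confusion = matrix(c(51L, 0L, 0L, 51L), 2), rmse = 6.15e-11,
                trainingSeconds = 3070, nEval = 102L)
  v <- selectOptimal(list(cnn, resnet))
  expect_identical(selectedModel(v), "cnn")
  expect_true(v@floorMet)
  # invariant to report ordering
  expect_identical(selectedModel(selectOptimal(list(resnet, cnn))), "cnn")
})

test_that("selection handles singletons, ties and a missed floor", {
  one <- classificationMetrics(c(0.9, 0.1), c(1, 0), modelId = "solo",
                               trainingSeconds = 10)
  expect_identical(selectedModel(selectOptimal(list(one))), "solo")

  a <- classificationMetrics(c(0.99, 0.01), c(1, 0), modelId = "sharp",
                             trainingSeconds = 10)
  b <- classificationMetrics(c(0.6, 0.4), c(1, 0), modelId = "blunt",
                             trainingSeconds = 10)
  expect_identical(selectedModel(selectOptimal(list(b, a))), "sharp")

  weak <- classificationMetrics(c(0.9, 0.9), c(1, 0), modelId = "weak",
                                trainingSeconds = 1)
  weaker <- suppressWarnings(
    classificationMetrics(c(0.1, 0.9), c(1, 0), modelId = "weaker",
                          trainingSeconds = 1))
  expect_warning(v <- selectOptimal(list(weaker, weak)), "floor")
  expect_identical(selectedModel(v), "weak")
  expect_false(v@floorMet)
})
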