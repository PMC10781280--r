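#' Probability root-mean-square error
#'
#' `sqrt(mean((p_i - y_i)^2))` between predicted class probabilities and
#' binary labels: the evaluation metric that separates models which all
#' reach perfect thresholded accuracy, since confident correct predictions
#' drive it toward zero.
#'
#' @param probabilities numeric vector in [0, 1].
#' @param labels binary vector (0/1) of the same length.
#' @return A non-negative scalar.
#' @examples
#' probabilityRMSE(c(0.5, 0.5), c(0, 1))  # 0.5
#' @export
probabilityRMSE <- function(probabilities, labels) {
  if (length(probabilities) == 0L || length(probabilities) != length(labels))
    stop("probabilities and labels must be non-empty and of equal length")
  sqrt(mean((probabilities - labels)^2))
}

#' Classification metrics at a probability threshold
#'
#' Thresholds probabilities at `threshold`, builds the 2x2 confusion
#' matrix (rows = truth, cols = prediction, positive class = 1), and
#' derives accuracy, precision, recall and F1 plus the probability RMSE.
#' Undefined 0/0 ratios (e.g. precision with no positive predictions) are
#' reported as 0 with a warning.
#'
#' @param probabilities numeric vector in [0, 1].
#' @param labels binary vector of the same length.
#' @param threshold decision threshold, default 0.5; predictions are
#'   positive when `p >= threshold`.
#' @param modelId identifier recorded in the report.
#' @param trainingSeconds wall-clock training time to carry along
#'   (NA when unknown).
#' @return An [EvalReport-class].
#' @examples
#' classificationMetrics(c(0.9, 0.1), c(1, 0))
#' @export
classificationMetrics <- function(probabilities, labels, threshold = 0.5,
                                  modelId = "model",
                                  trainingSeconds = NA_real_) {
  if (length(probabilities) == 0L || length(probabilities) != length(labels))
    stop("probabilities and labels must be non-empty and of equal length")
  pred <- as.integer(probabilities >= threshold)
  truth <- as.integer(labels)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  n <- length(truth)

  ratio0 <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s is 0/0 (no %s); reporting 0", what,
                      if (what == "precision") "positive predictions"
                      else "positive labels"), call. = FALSE)
      0
    } else num / den
  }
  precision <- ratio0(tp, tp + fp, "precision")
  recall <- ratio0(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("F1 is 0/0; reporting 0", call. = FALSE)
    0
  } else 2 * precision * recall / (precision + recall)

  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(truth = c("1", "0"),
                                      predicted = c("1", "0")))
  storage.mode(confusion) <- "integer"
  new("EvalReport", modelId = modelId, accuracy = (tp + tn) / n,
      precision = precision, recall = recall, f1 = f1,
      confusion = confusion,
      rmse = probabilityRMSE(probabilities, labels),
      trainingSeconds = trainingSeconds, nEval = n)
}

#' Select the model suited to real-time detection
#'
#' Ranks candidate reports under the real-time selection rule: candidates
#' meeting the accuracy floor are ordered primarily by training seconds
#' ascending (rapid retraining on newly collected data is the priority),
#' with probability RMSE ascending as tie-break — the ordering under which
#' a fast compact network beats a slower residual network that attains a
#' lower RMSE. If no candidate meets the floor, the verdict falls back to
#' the best-accuracy candidate and flags a warning. The result is
#' invariant to the order in which reports are supplied.
#'
#' @param reports non-empty list of [EvalReport-class].
#' @param accuracyFloor minimum accuracy for a candidate (default 1.0).
#' @return A [SelectionVerdict-class].
#' @examples
#' a <- classificationMetrics(c(1, 0), c(1, 0), modelId = "cnn",
#'                            trainingSeconds = 883)
#' b <- classificationMetrics(c(1, 0), c(1, 0), modelId = "resnet101",
#'                            trainingSeconds = 3070)
#' selectOptimal(list(a, b))
#' @export
selectOptimal <- function(reports, accuracyFloor = 1.0) {
  if (length(reports) == 0L) stop("reports must be non-empty")
  df <- do.call(rbind, lapply(reports, function(r) {
    stopifnot(is(r, "EvalReport"))
    data.frame(modelId = r@modelId, accuracy = r@accuracy, rmse = r@rmse,
               trainingSeconds = r@trainingSeconds,
               stringsAsFactors = FALSE)
  }))
  df$meetsFloor <- df$accuracy >= accuracyFloor
  floorMet <- any(df$meetsFloor)
  ord <- if (floorMet) {
    order(!df$meetsFloor, df$trainingSeconds, df$rmse, df$modelId)
  } else {
    order(-df$accuracy, df$trainingSeconds, df$rmse, df$modelId)
  }
  ranking <- df[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  if (!floorMet)
    warning(sprintf(
      "no candidate reaches the accuracy floor %.3f; selecting best accuracy '%s'",
      accuracyFloor, ranking$modelId[1]), call. = FALSE)
  new("SelectionVerdict", selected = ranking$modelId[1], ranking = ranking,
      accuracyFloor = accuracyFloor, floorMet = floorMet)
}

#' @rdname selectOptimal
#' @param verdict a [SelectionVerdict-class].
#' @return `selectedModel`: the selected model id.
#' @export
selectedModel <- function(verdict) {
  stopifnot(is(verdict, "SelectionVerdict"))
  verdict@selected
}
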