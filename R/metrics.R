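# Evaluation metrics: multi-class classification report, positioning error
# report, and multi-seed aggregation (mean +/- sd with t-based 95% CI).

#' Multi-class classification metrics
#'
#' Computes accuracy, per-class precision/recall/F1, their macro and micro
#' averages, macro one-vs-rest AUC, and the confusion matrix. Per-class
#' precision (recall) with an empty predicted (true) class is reported as 0,
#' the usual convention for sparse confusion rows.
#'
#' @param labels Factor (or vector) of true class labels.
#' @param predictions Vector of predicted labels, same length.
#' @param probabilities Optional `N x nClasses` matrix of class
#'   probabilities (columns named or ordered by class level) for the AUC.
#' @return A list with `accuracy`, `macroPrecision`, `macroRecall`,
#'   `macroF1`, `microF1`, `auc` (NA without probabilities), `perClass`
#'   (data frame: class, precision, recall, f1, support), and `confusion`.
#' @examples
#' computeMetrics(c("a", "a", "b"), c("a", "b", "b"))
#' @export
computeMetrics <- function(labels, predictions, probabilities = NULL) {
  if (length(labels) == 0L || length(labels) != length(predictions))
    stop("labels and predictions must be aligned and non-empty")
  # keep declared label levels (a class absent from this split still counts)
  if (!is.factor(labels)) labels <- factor(labels)
  classes <- levels(labels)
  extra <- setdiff(unique(as.character(predictions)), classes)
  if (length(extra)) {
    classes <- c(classes, extra)
    labels <- factor(labels, levels = classes)
  }
  predictions <- factor(as.character(predictions), levels = classes)
  cm <- table(true = labels, pred = predictions)
  acc <- sum(diag(cm)) / sum(cm)
  prec <- rec <- f1 <- numeric(length(classes))
  for (k in seq_along(classes)) {
    tp <- cm[k, k]
    predP <- sum(cm[, k]); truP <- sum(cm[k, ])
    prec[k] <- if (predP > 0) tp / predP else 0
    rec[k] <- if (truP > 0) tp / truP else 0
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  auc <- NA_real_
  if (!is.null(probabilities)) {
    probabilities <- as.matrix(probabilities)
    if (nrow(probabilities) != length(labels) ||
        ncol(probabilities) != length(classes))
      stop("probabilities must be N x nClasses")
    if (length(unique(labels)) < 2L)
      stop("AUC undefined: only one class present in labels")
    aucs <- vapply(seq_along(classes), function(k) {
      y <- as.integer(labels == classes[k])
      if (all(y == 1L) || all(y == 0L)) return(NA_real_)
      .binaryAuc(y, probabilities[, k])
    }, numeric(1L))
    auc <- mean(aucs, na.rm = TRUE)
  }
  list(accuracy = acc,
       macroPrecision = mean(prec), macroRecall = mean(rec),
       macroF1 = mean(f1),
       microF1 = acc,  # micro precision = recall = accuracy for single-label
       auc = auc,
       perClass = data.frame(class = classes, precision = prec, recall = rec,
                             f1 = f1, support = as.integer(rowSums(cm))),
       confusion = cm)
}

# rank-based AUC (equivalent to the Mann-Whitney statistic, ties averaged)
.binaryAuc <- function(y, score) {
  r <- rank(score, ties.method = "average")
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Positioning error report
#'
#' Error tables for an estimated trajectory against ground truth: per-axis
#' mean absolute error and RMSE, the 3D Euclidean error mean and standard
#' deviation, and the empirical fraction of samples whose 3D error falls
#' below a threshold (default 1.0 m).
#'
#' @param estimate,truth Aligned `K x 3` position matrices, meters.
#' @param threshold 3D error threshold for the fraction statistic, meters.
#' @return A list with `perAxis` (data frame: axis, mean_error_m, rmse_m),
#'   `mean3dError`, `sd3dError`, `fractionBelow`, `threshold`.
#' @examples
#' est <- matrix(c(0.3, 0.4, 0), 10, 3, byrow = TRUE)
#' positioningErrorReport(est, matrix(0, 10, 3))$mean3dError  # 0.5
#' @export
positioningErrorReport <- function(estimate, truth, threshold = 1.0) {
  estimate <- as.matrix(estimate); truth <- as.matrix(truth)
  if (!all(dim(estimate) == dim(truth)))
    stop("estimate and truth trajectories must be aligned (same dimensions)")
  err <- estimate - truth
  mae <- colMeans(abs(err))
  rmse <- sqrt(colMeans(err^2))
  e3 <- sqrt(rowSums(err^2))
  list(perAxis = data.frame(axis = c("x", "y", "z"), mean_error_m = mae,
                            rmse_m = rmse, row.names = NULL),
       mean3dError = mean(e3),
       sd3dError = if (length(e3) > 1L) stats::sd(e3) else 0,
       fractionBelow = mean(e3 < threshold),
       threshold = threshold)
}

#' Aggregate a metric across seeds: mean, sd, and t-based 95% CI
#'
#' The reporting convention for repeated runs with different random seeds:
#' mean +/- standard deviation and a t-distribution 95% confidence interval.
#' The sd over identical runs is exactly 0.
#'
#' @param values Numeric vector of per-seed metric values.
#' @param conf Confidence level.
#' @return A list with `mean`, `sd`, `ciLow`, `ciHigh`, `n`.
#' @export
aggregateSeedMetrics <- function(values, conf = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0L) stop("no values to aggregate")
  m <- mean(values)
  s <- if (n > 1L) stats::sd(values) else 0
  half <- if (n > 1L) stats::qt(1 - (1 - conf) / 2, df = n - 1L) * s / sqrt(n)
          else 0
  list(mean = m, sd = s, ciLow = m - half, ciHigh = m + half, n = n)
}

#' Paired t-test between two models' per-seed metrics
#'
#' Two-sided paired comparison across seeds, reported (p-value, mean
#' difference) but never used to gate anything automatically.
#'
#' @param a,b Aligned numeric vectors of per-seed metric values.
#' @return A list with `meanDiff`, `pValue`, `n`.
#' @export
pairedSeedTest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need >= 2 paired values")
  d <- a - b
  if (stats::sd(d) == 0) {
    # degenerate: identical differences; p-value 1 when diff 0, else 0
    return(list(meanDiff = mean(d), pValue = if (mean(d) == 0) 1 else 0,
                n = length(a)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(meanDiff = mean(d), pValue = tt$p.value, n = length(a))
}
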