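# Uncertainty and classification evaluation: interval coverage and width,
# noise-robustness (RNH), regression errors, confusion-matrix metrics and
# rank-based AUC. The interval z-value is fixed at 1.96 exactly (as the
# coverage/width formulas are printed), not the 0.975 normal quantile.

#' Empirical coverage of nominal 95% prediction intervals
#'
#' Fraction of observations with
#' `y_i` in `[yhat_i - 1.96 sigma_i, yhat_i + 1.96 sigma_i]`.
#'
#' @param mean predicted means (ml).
#' @param sd predicted standard deviations (ml), > 0.
#' @param truth observed values (ml).
#' @return coverage rate in \[0, 1\].
#' @export
interval_coverage <- function(mean, sd, truth) {
  n <- length(truth)
  if (n == 0L || length(mean) != n || length(sd) != n) {
    stop("`mean`, `sd`, `truth` must be non-empty and aligned", call. = FALSE)
  }
  if (any(sd <= 0)) stop("`sd` must be strictly positive", call. = FALSE)
  mean(truth >= mean - 1.96 * sd & truth <= mean + 1.96 * sd)
}

#' Mean width of nominal 95% prediction intervals
#'
#' Mean over observations of `2 * 1.96 * sigma_i`.
#'
#' @param sd predicted standard deviations (ml), > 0.
#' @return mean interval width (ml).
#' @export
interval_width <- function(sd) {
  if (length(sd) == 0L) stop("`sd` must be non-empty", call. = FALSE)
  if (any(sd <= 0)) stop("`sd` must be strictly positive", call. = FALSE)
  mean(2 * 1.96 * sd)
}

#' Rate of noise-induced error change (RNH)
#'
#' Mean relative change of the prediction error after controlled noise
#' injection: `mean(|(yhat_noise - y) - (yhat - y)| / |yhat - y|)`. Pairs
#' whose baseline error is below `eps` are excluded (their relative change
#' is undefined) and counted in the `n_excluded` attribute. Lower is more
#' robust.
#'
#' @param clean predictions on clean inputs.
#' @param noisy predictions on noise-injected inputs.
#' @param truth observed values.
#' @param eps baseline-error floor for inclusion (default 1e-8).
#' @return RNH rate (>= 0) with attribute `n_excluded`.
#' @export
rnh <- function(clean, noisy, truth, eps = 1e-8) {
  n <- length(truth)
  if (n == 0L || length(clean) != n || length(noisy) != n) {
    stop("inputs must be non-empty and aligned", call. = FALSE)
  }
  base <- clean - truth
  keep <- abs(base) >= eps
  if (!any(keep)) stop("all baseline errors below `eps`; RNH undefined", call. = FALSE)
  val <- mean(abs((noisy[keep] - truth[keep]) - base[keep]) / abs(base[keep]))
  attr(val, "n_excluded") <- sum(!keep)
  val
}

#' Confusion matrix from counts or predictions
#'
#' @param tn,fp,fn,tp non-negative integer counts; alternatively give
#'   `predicted` and `actual` binary vectors.
#' @param predicted,actual optional binary vectors from which the counts
#'   are tabulated.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tn = NULL, fp = NULL, fn = NULL, tp = NULL,
                             predicted = NULL, actual = NULL) {
  if (!is.null(predicted)) {
    stopifnot(length(predicted) == length(actual))
    predicted <- as.integer(predicted != 0)
    actual <- as.integer(actual != 0)
    tn <- sum(predicted == 0 & actual == 0)
    fp <- sum(predicted == 1 & actual == 0)
    fn <- sum(predicted == 0 & actual == 1)
    tp <- sum(predicted == 1 & actual == 1)
  }
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) == 0) {
    stop("counts must be non-negative integers with a positive total", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(c("actual 0", "actual 1"),
                              c("predicted 0", "predicted 1")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Recall (sensitivity) tp/(tp+fn), specificity tn/(tn+fp), precision
#' tp/(tp+fp) and accuracy (tp+tn)/total. A metric whose denominator is
#' zero is reported as NA (undefined), never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return named list with `recall`, `specificity`, `precision`,
#'   `accuracy`.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(recall = safe(cm$tp, cm$tp + cm$fn),
       specificity = safe(cm$tn, cm$tn + cm$fp),
       precision = safe(cm$tp, cm$tp + cm$fp),
       accuracy = (cm$tp + cm$tn) / (cm$tn + cm$fp + cm$fn + cm$tp))
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted half. Identical to exhaustive
#' pair counting.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (both classes must be present).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  if (length(scores) != length(labels)) stop("inputs must be aligned", call. = FALSE)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean squared and mean absolute error
#'
#' @param pred predictions.
#' @param truth observed values, aligned with `pred`.
#' @return list with `mse` and `mae`.
#' @export
regression_errors <- function(pred, truth) {
  if (length(pred) == 0L || length(pred) != length(truth)) {
    stop("inputs must be non-empty and aligned", call. = FALSE)
  }
  e <- pred - truth
  list(mse = mean(e^2), mae = mean(abs(e)))
}

#' Full evaluation report for one model run
#'
#' Bundles regression errors of the predicted mean paths, interval coverage
#' and width, optional noise-robustness, and threshold-based classification
#' metrics with rank AUC.
#'
#' @param pred_mean predicted means at the evaluated points (ml).
#' @param pred_sd predicted standard deviations (ml).
#' @param truth observed values (ml).
#' @param scores optional expansion probabilities P_j.
#' @param labels optional binary expansion labels.
#' @param noisy_mean optional predictions after noise injection (for RNH).
#' @param threshold classification cut-off on the scores (default 0.5).
#' @return object of class `evaluation_report`.
#' @export
evaluation_report <- function(pred_mean, pred_sd, truth, scores = NULL,
                              labels = NULL, noisy_mean = NULL,
                              threshold = 0.5) {
  err <- regression_errors(pred_mean, truth)
  rep <- list(mse = err$mse, mae = err$mae,
              coverage = interval_coverage(pred_mean, pred_sd, truth),
              mean_width = interval_width(pred_sd),
              rnh = if (is.null(noisy_mean)) NA_real_ else
                as.numeric(rnh(pred_mean, noisy_mean, truth)),
              recall = NA_real_, specificity = NA_real_,
              precision = NA_real_, accuracy = NA_real_, auc = NA_real_,
              threshold = threshold)
  if (!is.null(scores) && !is.null(labels)) {
    cm <- confusion_matrix(predicted = scores >= threshold, actual = labels)
    rep[c("recall", "specificity", "precision", "accuracy")] <-
      confusion_metrics(cm)
    rep$confusion <- unclass(cm)
    if (length(unique(as.integer(labels != 0))) == 2L) {
      rep$auc <- roc_auc(scores, labels)
    }
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  volume fit: MSE %.4f, MAE %.4f (ml)\n", x$mse, x$mae))
  cat(sprintf("  95%% intervals: coverage %.3f, mean width %.3f ml\n",
              x$coverage, x$mean_width))
  if (!is.na(x$rnh)) cat(sprintf("  noise robustness RNH: %.4f\n", x$rnh))
  if (!is.na(x$auc)) {
    cat(sprintf("  expansion classification (cut-off %.2f): recall %.3f, specificity %.3f, precision %.3f, accuracy %.3f, AUC %.3f\n",
                x$threshold, x$recall, x$specificity, x$precision, x$accuracy,
                x$auc))
  }
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report an [evaluation_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
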