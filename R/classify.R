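#' Youden-index classification cutoff
#'
#' Finds the cutoff maximising the Youden index J = TPR - FPR under the
#' prediction rule value > cutoff => positive. Cutoffs are taken at the
#' observed values; when several achieve the maximal J the largest cutoff
#' (fewest predicted positives) is reported.
#'
#' @inheritParams roc_curve
#' @return the selected cutoff.
#' @examples
#' youden_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)) # 3
#' @export
youden_cutoff <- function(values, labels) {
  d <- as_binary_labels(labels)
  check_dataset(values, d)
  m <- sum(d)
  n <- length(d) - m
  cand <- sort(unique(values))
  tpr <- vapply(cand, function(cc) sum(values > cc & d == 1L) / m, 0)
  fpr <- vapply(cand, function(cc) sum(values > cc & d == 0L) / n, 0)
  j <- tpr - fpr
  best <- which(j >= max(j) - 1e-12)
  cand[max(best)]
}

#' Split samples into classifiable and unclassifiable
#'
#' A sample is classifiable by a restricted biomarker exactly when its
#' value lies in the fitted informative range: `(r_opt, Inf)` for a high
#' part optimum, `(-Inf, r_opt]` for a low part optimum.
#'
#' @param values numeric biomarker values.
#' @param fit an [rroc()] fit of the same biomarker.
#' @return logical vector, `TRUE` where classifiable.
#' @export
split_classifiable <- function(values, fit) {
  stopifnot(inherits(fit, "rroc"))
  in_informative_range(values, fit$informative_range, fit$part_opt)
}

#' Confusion-matrix performance metrics
#'
#' Standard 2x2 metrics for binary predictions: correct classification rate
#' (CCR), sensitivity (TPR), specificity (TNR), positive and negative
#' predictive values. Rates with a zero denominator are reported as `NA`
#' rather than 0.
#'
#' @param predictions predicted classes (binary/logical).
#' @param labels true classes (binary/logical, or two-level factor).
#' @param cutoff optional cutoff to record alongside the metrics.
#' @return An object of class `confusion_metrics`: a list with `counts`
#'   (tp, fp, tn, fn), `ccr`, `tpr`, `tnr`, `ppv`, `npv` and `cutoff`.
#' @examples
#' # sensitivity 11/12, specificity 9/14, PPV 11/16, NPV 9/10, CCR 20/26
#' confusion_metrics(rep(c(1, 0, 0, 1), c(11, 1, 9, 5)),
#'                   rep(c(1, 1, 0, 0), c(11, 1, 9, 5)))
#' @export
confusion_metrics <- function(predictions, labels, cutoff = NA_real_) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  pred <- as_binary_labels(predictions)
  d <- as_binary_labels(labels)
  tp <- sum(pred == 1L & d == 1L)
  fp <- sum(pred == 1L & d == 0L)
  tn <- sum(pred == 0L & d == 0L)
  fn <- sum(pred == 0L & d == 1L)
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  out <- list(
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
    ccr = rate(tp + tn, tp + fp + tn + fn),
    tpr = rate(tp, tp + fn),
    tnr = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    cutoff = cutoff
  )
  class(out) <- "confusion_metrics"
  out
}

#' @export
print.confusion_metrics <- function(x, indent = "", ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("%sTP %d  FP %d  TN %d  FN %d\n", indent,
              x$counts["tp"], x$counts["fp"], x$counts["tn"], x$counts["fn"]))
  cat(sprintf("%sCCR %s  sens %s  spec %s  PPV %s  NPV %s\n", indent,
              pct(x$ccr), pct(x$tpr), pct(x$tnr), pct(x$ppv), pct(x$npv)))
  invisible(x)
}

#' Predict from a restricted ROC fit
#'
#' Classifies new samples with the fitted biomarker: samples outside the
#' informative range are unclassifiable (`NA` prediction); classifiable
#' samples are predicted positive when the value exceeds the Youden cutoff
#' fitted on the classifiable training samples.
#'
#' @param object an [rroc()] fit.
#' @param newdata numeric vector of biomarker values; defaults to the
#'   training values.
#' @param ... unused.
#' @return a data frame with `value`, `classifiable` and `prediction`
#'   (integer 0/1, `NA` when unclassifiable).
#' @export
predict.rroc <- function(object, newdata = NULL, ...) {
  values <- if (is.null(newdata)) object$values else as.numeric(newdata)
  keep <- split_classifiable(values, object)
  pred <- ifelse(keep, as.integer(values > object$cutoff), NA_integer_)
  data.frame(value = values, classifiable = keep, prediction = pred)
}
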