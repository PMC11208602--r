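#' Fit a restricted ROC model
#'
#' The main fitting function of the package. For a single biomarker with a
#' binary outcome it (1) builds the empirical ROC curve, (2) scans every
#' candidate restriction, computing the restricted AUC of the high
#' (values > r) and low (values <= r) parts and standardising each by its
#' null standard deviation (rzAUC), (3) selects the optimal restriction as
#' the maximum absolute rzAUC, defining the biomarker's informative range,
#' and (4) attaches permutation p-values to both the unrestricted AUC and
#' the optimal rzAUC by reshuffling class labels.
#'
#' The permutation p-value of the optimum compares, for each shuffle, the
#' maximum absolute rzAUC over all candidate restrictions and both parts
#' against the observed optimum; this accounts for the selection bias of
#' maximising over restrictions, for which no closed-form null is used.
#' Both p-values use the plus-one rule \eqn{(n_{above}+1)/(n_{total}+1)} by
#' default; `counting = "midp"` gives half weight to ties.
#'
#' @param x a numeric biomarker vector, or a formula `label ~ marker`.
#' @param ... passed between methods.
#' @return An object of class `rroc`. See Details for components; use
#'   [print.rroc()], [summary.rroc()], [plot.rroc()] and [predict.rroc()].
#' @examples
#' set.seed(1)
#' d <- simulate_two_class(two_class_scenarios()$large_mixture, seed = 1)
#' fit <- rroc(d$value, d$class, n_permutations = 200, seed = 1)
#' fit
#' @export
rroc <- function(x, ...) UseMethod("rroc")

#' @rdname rroc
#' @param data a data frame holding the formula variables.
#' @param positive which label level is the positive (diseased) class; by
#'   default the last sorted level of a character/factor label, or `1` for
#'   numeric 0/1 labels.
#' @export
rroc.formula <- function(x, data, positive = NULL, ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2L) stop("formula must be of the form label ~ marker")
  fit <- rroc.default(mf[[2L]], mf[[1L]], positive = positive, ...)
  fit$call <- match.call()
  fit
}

#' @rdname rroc
#' @param labels binary class labels (0/1, logical, or two-level
#'   character/factor).
#' @param n_permutations number of label permutations for the p-values
#'   (default 10000); 0 skips permutation testing.
#' @param seed optional integer seed for the permutations.
#' @param counting `"plus_one"` (default) or `"midp"` permutation p-value
#'   counting rule.
#' @param alternative for the unrestricted AUC p-value: `"greater"`
#'   (default; permuted AUC >= observed) or `"two.sided"` (on |AUC - 0.5|).
#' @export
rroc.default <- function(x, labels, positive = NULL,
                         n_permutations = 10000L, seed = NULL,
                         counting = c("plus_one", "midp"),
                         alternative = c("greater", "two.sided"), ...) {
  counting <- match.arg(counting)
  alternative <- match.arg(alternative)
  values <- as.numeric(x)
  d <- as_binary_labels(labels, positive)
  check_dataset(values, d)

  scan <- scan_restrictions(values, d)
  opt <- optimal_restriction(scan)

  fit <- list(
    call = match.call(),
    values = values,
    labels = d,
    m = attr(scan, "m"),
    n = attr(scan, "n"),
    auc = attr(scan, "auc"),
    scan = scan,
    r_opt = opt$r_opt,
    part_opt = opt$part_opt,
    rauc_opt = opt$rauc_opt,
    rzauc_opt = opt$rzauc_opt,
    fpr_opt = opt$fpr_opt,
    tpr_opt = opt$tpr_opt,
    n_kept = opt$n_kept,
    informative_range = opt$informative_range,
    p_unrestricted = NA_real_,
    p_restricted = NA_real_,
    n_permutations = as.integer(n_permutations),
    counting = counting
  )

  if (n_permutations > 0L) {
    if (!is.null(seed)) set.seed(seed)
    pv <- permutation_pvalues_(values, d, n_permutations,
                               obs_auc = fit$auc,
                               obs_abs_rz = abs(fit$rzauc_opt),
                               counting = counting,
                               alternative = alternative)
    fit$p_unrestricted <- pv$p_unrestricted
    fit$p_restricted <- pv$p_restricted
  }

  # classification cutoff (Youden) on the classifiable training samples
  keep <- in_informative_range(values, fit$informative_range, fit$part_opt)
  fit$cutoff <- if (sum(d[keep]) >= 1L && sum(1L - d[keep]) >= 1L) {
    youden_cutoff(values[keep], d[keep])
  } else {
    NA_real_
  }
  class(fit) <- "rroc"
  fit
}

permutation_pvalues_ <- function(values, d, n_perm, obs_auc, obs_abs_rz,
                                 counting, alternative) {
  prep <- scan_prep(values)
  ds <- d[prep$ord]
  nn <- length(ds)
  perm_auc <- numeric(n_perm)
  perm_abs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    st <- scan_stats(prep, ds[sample.int(nn)])
    perm_auc[b] <- st$auc
    perm_abs[b] <- max(abs(st$rzauc_high), abs(st$rzauc_low), na.rm = TRUE)
  }
  if (alternative == "two.sided") {
    perm_auc <- abs(perm_auc - 0.5)
    obs_auc <- abs(obs_auc - 0.5)
  }
  list(
    p_unrestricted = count_pvalue(perm_auc, obs_auc, counting),
    p_restricted = count_pvalue(perm_abs, obs_abs_rz, counting)
  )
}

count_pvalue <- function(perm, obs, counting = c("plus_one", "midp")) {
  counting <- match.arg(counting)
  n_total <- length(perm)
  if (counting == "plus_one") {
    (sum(perm >= obs) + 1) / (n_total + 1)
  } else {
    (sum(perm > obs) + 0.5 * sum(perm == obs) + 0.5) / (n_total + 1)
  }
}

#' Benjamini-Hochberg adjustment of permutation p-values
#'
#' Step-up false discovery rate q-values across a family of tested
#' biomarkers (a thin validating wrapper around [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Screen many biomarkers for restricted discriminative power
#'
#' Fits [rroc()] to every marker column of a data frame against one label
#' column and tabulates the unrestricted AUC, the optimal restriction, the
#' permutation p-values and their BH q-values.
#'
#' @param data a data frame, one row per sample.
#' @param label name of the binary label column.
#' @param markers marker column names (default: all other numeric columns).
#' @inheritParams rroc.default
#' @return a data frame with one row per marker: `marker`, `auc`,
#'   `p_unrestricted`, `r_opt`, `part`, `rauc_opt`, `rzauc_opt`,
#'   `range_lo`, `range_hi`, `n_kept`, `p_restricted`, plus
#'   `q_unrestricted` and `q_restricted` BH q-values.
#' @export
rroc_screen <- function(data, label, markers = NULL, positive = NULL,
                        n_permutations = 10000L, seed = NULL, ...) {
  stopifnot(is.data.frame(data), label %in% names(data))
  if (is.null(markers)) {
    markers <- names(data)[vapply(data, is.numeric, logical(1L))]
    markers <- setdiff(markers, label)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(markers, function(mk) {
    fit <- rroc.default(data[[mk]], data[[label]], positive = positive,
                        n_permutations = n_permutations, seed = NULL, ...)
    data.frame(
      marker = mk, auc = fit$auc, p_unrestricted = fit$p_unrestricted,
      r_opt = fit$r_opt, part = fit$part_opt, rauc_opt = fit$rauc_opt,
      rzauc_opt = fit$rzauc_opt,
      range_lo = fit$informative_range[1L],
      range_hi = fit$informative_range[2L],
      n_kept = fit$n_kept, p_restricted = fit$p_restricted
    )
  })
  out <- do.call(rbind, rows)
  if (n_permutations > 0L) {
    out$q_unrestricted <- fdr_adjust(out$p_unrestricted)
    out$q_restricted <- fdr_adjust(out$p_restricted)
  }
  out
}

#' @export
print.rroc <- function(x, ...) {
  cat("Restricted ROC fit\n")
  cat(sprintf("  %d positive / %d negative samples; unrestricted AUC = %.4f\n",
              x$m, x$n, x$auc))
  cat(sprintf("  optimal restriction: r = %.4g, part = %s (keeps %d of %d)\n",
              x$r_opt, x$part_opt, x$n_kept, x$m + x$n))
  cat(sprintf("  informative range: (%.4g, %.4g%s\n",
              x$informative_range[1L], x$informative_range[2L],
              if (x$part_opt == "low") "]" else ")"))
  cat(sprintf("  rAUC = %.4f, rzAUC = %.3f\n", x$rauc_opt, x$rzauc_opt))
  if (!is.na(x$p_restricted)) {
    cat(sprintf("  permutation p-values (%d shuffles): unrestricted %.4g, restricted %.4g\n",
                x$n_permutations, x$p_unrestricted, x$p_restricted))
  }
  invisible(x)
}

#' @export
summary.rroc <- function(object, ...) {
  keep <- in_informative_range(object$values, object$informative_range,
                               object$part_opt)
  cm <- if (!is.na(object$cutoff)) {
    confusion_metrics(object$values[keep] > object$cutoff,
                      object$labels[keep], cutoff = object$cutoff)
  }
  out <- list(fit = object, n_classifiable = sum(keep),
              n_unclassifiable = sum(!keep), confusion = cm)
  class(out) <- "summary.rroc"
  out
}

#' @export
print.summary.rroc <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  classifiable: %d, unclassifiable: %d\n",
              x$n_classifiable, x$n_unclassifiable))
  if (!is.null(x$confusion)) {
    cat("  performance on classifiable samples (Youden cutoff):\n")
    print(x$confusion, indent = "    ")
  }
  invisible(x)
}

#' Plot method for restricted ROC fits
#'
#' `which = "rzauc"` draws the rzAUC of the high and low parts against the
#' candidate restriction values with the optimum marked; `which = "roc"`
#' draws the full ROC curve with the optimal restriction point.
#'
#' @param x an `rroc` object.
#' @param which `"rzauc"` or `"roc"`.
#' @param ... further graphical parameters.
#' @export
plot.rroc <- function(x, which = c("rzauc", "roc"), ...) {
  which <- match.arg(which)
  sc <- x$scan
  if (which == "rzauc") {
    finite_r <- sc$r[is.finite(sc$r)]
    xr <- sc$r
    xr[!is.finite(xr)] <- min(finite_r) - diff(range(finite_r)) * 0.05
    ylim <- range(c(sc$rzauc_high, sc$rzauc_low), na.rm = TRUE)
    graphics::plot(xr, sc$rzauc_high, type = "l", col = "darkorange",
                   xlab = "restriction r", ylab = "rzAUC", ylim = ylim, ...)
    graphics::lines(xr, sc$rzauc_low, col = "steelblue")
    graphics::abline(v = x$r_opt, col = "red", lty = 2)
    graphics::legend("topright", legend = c("high part", "low part"),
                     col = c("darkorange", "steelblue"), lty = 1, bty = "n")
  } else {
    rc <- roc_curve(x$values, x$labels)
    plot(rc, ...)
    graphics::points(x$fpr_opt, x$tpr_opt, col = "red", pch = 19)
  }
  invisible(x)
}

#' @export
coef.rroc <- function(object, ...) {
  c(r_opt = object$r_opt, rauc = object$rauc_opt, rzauc = object$rzauc_opt,
    auc = object$auc, cutoff = object$cutoff)
}
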