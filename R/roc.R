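#' Empirical ROC curve
#'
#' Builds the empirical receiver operating characteristic curve of a
#' continuous biomarker against a binary class label. A sample is called
#' positive when its value is at or above the cutoff, so the curve runs from
#' (0, 0) at cutoff `+Inf` to (1, 1) at cutoff `-Inf`, with one point per
#' distinct observed value (tied values collapse to a single vertex).
#'
#' @param values numeric vector of biomarker measurements (finite).
#' @param labels binary class indicator, coercible via [as_binary_labels()];
#'   1 = positive (diseased), 0 = negative.
#' @return An object of class `roc_curve`: a list with `thresholds`
#'   (decreasing, starting at `Inf`), `fpr`, `tpr` (both nondecreasing from
#'   0 to 1), and the class counts `m` (positives) and `n` (negatives).
#' @seealso [auc()], [rroc()]
#' @examples
#' rc <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
#' auc(rc)
#' @export
roc_curve <- function(values, labels) {
  d <- as_binary_labels(labels)
  check_dataset(values, d)
  ord <- order(values, decreasing = TRUE)
  ys <- values[ord]
  ds <- d[ord]
  m <- sum(ds)
  n <- length(ds) - m
  # vertex per distinct value: counts of samples >= that value
  ends <- which(c(ys[-1L] != ys[-length(ys)], TRUE))
  tp <- cumsum(ds)[ends]
  fp <- cumsum(1 - ds)[ends]
  structure(list(
    thresholds = c(Inf, ys[ends]),
    fpr = c(0, fp / n),
    tpr = c(0, tp / m),
    m = m, n = n
  ), class = "roc_curve")
}

#' Area under an ROC curve
#'
#' Trapezoidal area under an empirical ROC curve. With tied values collapsed
#' to single vertices this equals the normalised Mann-Whitney pair statistic
#' P\[Y_pos > Y_neg\] with half credit for ties.
#'
#' @param curve an object returned by [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (curve$tpr[-1L] + curve$tpr[-length(curve$tpr)]) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("Empirical ROC curve:", length(x$thresholds), "points,",
      x$m, "positive /", x$n, "negative samples\n")
  cat(sprintf("AUC = %.4f\n", auc(x)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlab = "FPR", ylab = "TPR", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Closed-form AUC for two Gaussian classes
#'
#' Exact area under the ROC curve when the negative class is
#' Normal(`mu_neg`, `sd_neg`) and the positive class is
#' Normal(`mu_pos`, `sd_pos`):
#' \deqn{AUC = \Phi\left((\mu_+ - \mu_-) / \sqrt{\sigma_-^2 + \sigma_+^2}\right)}
#'
#' The `scale` switch controls whether the dispersion arguments are read as
#' standard deviations (default) or variances.
#'
#' @param mu_neg,sd_neg mean and dispersion of the negative class.
#' @param mu_pos,sd_pos mean and dispersion of the positive class.
#' @param scale `"sd"` (default) or `"variance"`.
#' @return AUC in (0, 1).
#' @examples
#' gaussian_auc(5, 1, 6, 1) # 0.760
#' gaussian_auc(5, 1, 6, 2) # 0.673
#' @export
gaussian_auc <- function(mu_neg, sd_neg, mu_pos, sd_pos,
                         scale = c("sd", "variance")) {
  scale <- match.arg(scale)
  if (any(c(sd_neg, sd_pos) <= 0)) {
    stop("class dispersions must be strictly positive")
  }
  v_neg <- if (scale == "sd") sd_neg^2 else sd_neg
  v_pos <- if (scale == "sd") sd_pos^2 else sd_pos
  stats::pnorm((mu_pos - mu_neg) / sqrt(v_neg + v_pos))
}

#' Closed-form AUC for two Gaussian mixture classes
#'
#' AUC between two classes each distributed as a finite mixture of normals,
#' computed componentwise:
#' \deqn{AUC = \sum_i \sum_j w^-_i w^+_j
#'   \Phi\left((\mu^+_j - \mu^-_i)/\sqrt{\sigma^{-2}_i + \sigma^{+2}_j}\right)}
#'
#' @param neg,pos data frames with columns `weight`, `mean`, `sd` (one row
#'   per mixture component; weights must sum to 1).
#' @param scale `"sd"` (default) or `"variance"` interpretation of `sd`.
#' @return AUC in (0, 1).
#' @export
gaussian_mixture_auc <- function(neg, pos, scale = c("sd", "variance")) {
  scale <- match.arg(scale)
  check_mixture(neg)
  check_mixture(pos)
  total <- 0
  for (i in seq_len(nrow(neg))) {
    for (j in seq_len(nrow(pos))) {
      total <- total + neg$weight[i] * pos$weight[j] *
        gaussian_auc(neg$mean[i], neg$sd[i], pos$mean[j], pos$sd[j],
                     scale = scale)
    }
  }
  total
}

#' Restricted AUC
#'
#' AUC of the restricted ROC curve at restriction `r`. The restriction
#' splits samples into a high part (values > r) and a low part (values <=
#' r). The restricted AUC of a part is the two-way partial area of the full
#' curve delimited by the restriction, rescaled by the spanned FPR and TPR
#' ranges; this equals the plain AUC computed on only that part's samples.
#'
#' @param values,labels the biomarker and binary labels (see [roc_curve()]).
#' @param r restriction value.
#' @param part `"high"` (keep values > r) or `"low"` (keep values <= r).
#' @return restricted AUC in \[0, 1\].
#' @seealso [rzauc()], [scan_restrictions()]
#' @export
rauc <- function(values, labels, r, part = c("high", "low")) {
  part <- match.arg(part)
  restricted_point(values, as_binary_labels(labels), r, part)$rauc
}

#' Sample-size standardised restricted AUC (rzAUC)
#'
#' Standardises the restricted AUC by its null standard deviation so that
#' restrictions retaining different numbers of samples become comparable:
#' \deqn{rzAUC_X(r) = (rAUC_X(r) - 0.5) / \sqrt{(m_X + n_X + 1)/(12 m_X n_X)}}
#' where \eqn{m_X, n_X} are the positive and negative counts in part X. The
#' null variance is the Mann-Whitney approximation; it is reasonably
#' accurate from about 6 samples per group, and a warning is emitted below
#' that.
#'
#' @inheritParams rauc
#' @return the standardised score (sign follows rAUC - 0.5).
#' @export
rzauc <- function(values, labels, r, part = c("high", "low")) {
  part <- match.arg(part)
  pt <- restricted_point(values, as_binary_labels(labels), r, part)
  if (pt$m_x < 6L || pt$n_x < 6L) {
    warning("fewer than 6 samples per group in the '", part,
            "' part; the null-variance approximation may be inaccurate")
  }
  (pt$rauc - 0.5) / sqrt(rzauc_null_var(pt$m_x, pt$n_x))
}

rzauc_null_var <- function(m, n) (m + n + 1) / (12 * m * n)

# Restricted quantities at a single restriction r, via the scaled two-way
# partial area of the empirical ROC curve. The point (#neg > r / n,
# #pos > r / m) is always a vertex of the curve, so the partial area is a
# partial trapezoid sum.
restricted_point <- function(values, d, r, part) {
  check_dataset(values, d)
  rc <- roc_curve(values, d)
  m <- rc$m
  n <- rc$n
  p_hi <- sum(values > r & d == 1L)
  n_hi <- sum(values > r & d == 0L)
  if (part == "high") {
    m_x <- p_hi
    n_x <- n_hi
  } else {
    m_x <- m - p_hi
    n_x <- n - n_hi
  }
  if (m_x < 1L || n_x < 1L) {
    stop("unrestrictable split: the '", part,
         "' part needs at least one positive and one negative sample")
  }
  beta <- n_hi / n      # S_Dbar(r), FPR spanned by the high part
  sd_r <- p_hi / m      # S_D(r), TPR spanned by the high part
  widths <- diff(rc$fpr)
  heights <- (rc$tpr[-1L] + rc$tpr[-length(rc$tpr)]) / 2
  areas <- widths * heights
  cum <- cumsum(areas)
  # vertex index of the restriction point on the curve
  k <- match(TRUE, abs(rc$fpr - beta) < 1e-12 & abs(rc$tpr - sd_r) < 1e-12)
  pa_high <- if (k == 1L) 0 else cum[k - 1L]
  if (part == "high") {
    rauc_x <- pa_high / (beta * sd_r)
  } else {
    pa_low <- (cum[length(cum)] - pa_high) - sd_r * (1 - beta)
    rauc_x <- pa_low / ((1 - beta) * (1 - sd_r))
  }
  list(rauc = rauc_x, m_x = m_x, n_x = n_x, fpr = beta, tpr = sd_r)
}

as_binary_labels <- function(labels, positive = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) return(as.integer(labels))
  if (is.character(labels)) {
    lev <- sort(unique(labels))
    if (is.null(positive)) {
      if (length(lev) > 2L) {
        stop("label vector has more than two levels: ",
             paste(lev, collapse = ", "))
      }
      positive <- lev[length(lev)]
    }
    return(as.integer(labels == positive))
  }
  if (!is.null(positive)) return(as.integer(labels == positive))
  if (!all(labels %in% c(0, 1))) {
    stop("numeric labels must be 0/1 (0 = negative, 1 = positive)")
  }
  as.integer(labels)
}

check_dataset <- function(values, d) {
  if (length(values) != length(d)) {
    stop("values and labels must have equal length")
  }
  if (!all(is.finite(values))) stop("biomarker values must be finite")
  m <- sum(d == 1L)
  n <- sum(d == 0L)
  if (m < 1L || n < 1L) {
    stop("degenerate labels: need at least one positive and one negative sample")
  }
  invisible(c(m = m, n = n))
}

check_mixture <- function(comp) {
  stopifnot(is.data.frame(comp),
            all(c("weight", "mean", "sd") %in% names(comp)))
  if (abs(sum(comp$weight) - 1) > 1e-8) {
    stop("mixture weights must sum to 1")
  }
  if (any(comp$sd <= 0)) stop("mixture component scales must be positive")
  invisible(comp)
}
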