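# Vectorised restriction scan.
#
# Every distinct observed biomarker value v (plus the keep-all sentinel
# -Inf) is a candidate restriction r splitting the samples into a high part
# {Y > r} and a low part {Y <= r}. Each candidate's high part corresponds
# exactly to one vertex of the empirical ROC curve, so all restricted AUCs
# are cumulative partial trapezoid areas of the full curve, rescaled to the
# unit square. One sort of the values is shared across label permutations.

scan_prep <- function(values) {
  ord <- order(values, decreasing = TRUE)
  ys <- values[ord]
  ends <- which(c(ys[-1L] != ys[-length(ys)], TRUE))
  # candidate r whose high part equals vertex i: the high part of vertex i
  # is {Y >= v_i} = {Y > v_(i+1)}, so r runs over the distinct values
  # (vertex 0, empty high part, pairs with r = max value) plus the keep-all
  # sentinel -Inf at vertex J
  vals <- ys[ends]
  list(ord = ord, ends = ends, r = c(vals, -Inf), values = vals)
}

# Statistics at every candidate for one label assignment (ds in the sorted
# order of scan_prep). Returns per-vertex vectors of length J + 1.
scan_stats <- function(prep, ds) {
  nn <- length(ds)
  m <- sum(ds)
  n <- nn - m
  tp <- c(0L, cumsum(ds)[prep$ends])
  fp <- c(0L, (seq_len(nn) - cumsum(ds))[prep$ends])
  fpr <- fp / n
  tpr <- tp / m
  j1 <- length(fpr)
  pa <- c(0, cumsum(diff(fpr) * (tpr[-1L] + tpr[-j1]) / 2))
  auc_full <- pa[j1]

  m_high <- tp
  n_high <- fp
  m_low <- m - tp
  n_low <- n - fp

  rauc_high <- ifelse(m_high >= 1L & n_high >= 1L,
                      pa / (fpr * tpr), NA_real_)
  rauc_low <- ifelse(m_low >= 1L & n_low >= 1L,
                     ((auc_full - pa) - tpr * (1 - fpr)) /
                       ((1 - fpr) * (1 - tpr)), NA_real_)
  rz_high <- (rauc_high - 0.5) / sqrt(rzauc_null_var(m_high, n_high))
  rz_low <- (rauc_low - 0.5) / sqrt(rzauc_null_var(m_low, n_low))

  list(m = m, n = n, fpr = fpr, tpr = tpr, auc = auc_full,
       m_high = m_high, n_high = n_high, m_low = m_low, n_low = n_low,
       rauc_high = rauc_high, rauc_low = rauc_low,
       rzauc_high = rz_high, rzauc_low = rz_low)
}

# Argmax of |rzAUC| over candidates and parts. Ties prefer the candidate
# retaining more samples, then the smaller restriction value.
scan_opt <- function(prep, st) {
  nn <- st$m + st$n
  kept <- cbind(high = st$m_high + st$n_high,
                low = nn - (st$m_high + st$n_high))
  absrz <- cbind(high = abs(st$rzauc_high), low = abs(st$rzauc_low))
  best <- max(absrz, na.rm = TRUE)
  # tolerance-based ties so the argmax is invariant to the float noise of
  # algebraically equivalent paths (e.g. class relabelling)
  tol <- max(1e-12, 1e-9 * best)
  cand <- which(!is.na(absrz) & absrz >= best - tol, arr.ind = TRUE)
  if (nrow(cand) > 1L) {
    k <- kept[cand]
    cand <- cand[k == max(k), , drop = FALSE]
    if (nrow(cand) > 1L) {
      r_c <- prep$r[cand[, 1L]]
      cand <- cand[which.min(r_c), , drop = FALSE]
    }
  }
  i <- cand[1L, 1L]
  part <- c("high", "low")[cand[1L, 2L]]
  list(
    r_opt = unname(prep$r[i]),
    part_opt = part,
    rauc_opt = unname(if (part == "high") st$rauc_high[i] else st$rauc_low[i]),
    rzauc_opt = unname(if (part == "high") st$rzauc_high[i] else st$rzauc_low[i]),
    fpr_opt = unname(st$fpr[i]),
    tpr_opt = unname(st$tpr[i]),
    n_kept = unname(kept[i, part])
  )
}

#' Scan all restrictions of a biomarker
#'
#' Computes the restricted AUC and the standardised rzAUC of the high part
#' (values > r) and the low part (values <= r) for every candidate
#' restriction r: each distinct observed value plus a sentinel below the
#' minimum (`-Inf`) so the unrestricted dataset is always a candidate.
#' Candidates whose part lacks a positive or a negative sample are reported
#' as `NA` rather than dropped, so the side counts always sum to the class
#' totals.
#'
#' @inheritParams roc_curve
#' @return A data frame of class `restriction_scan` with one row per
#'   candidate: `r`, the ROC coordinates `fpr`/`tpr` of the split point,
#'   side counts `m_high`, `n_high`, `m_low`, `n_low`, and
#'   `rauc_high`, `rzauc_high`, `rauc_low`, `rzauc_low`.
#' @seealso [rroc()] for the full fit including the optimum and permutation
#'   p-values.
#' @examples
#' scan_restrictions(c(1, 2, 5, 6, 3, 4, 7, 8), rep(0:1, each = 4))
#' @export
scan_restrictions <- function(values, labels) {
  d <- as_binary_labels(labels)
  check_dataset(values, d)
  prep <- scan_prep(values)
  st <- scan_stats(prep, d[prep$ord])
  out <- data.frame(
    r = prep$r,
    fpr = st$fpr, tpr = st$tpr,
    m_high = st$m_high, n_high = st$n_high,
    m_low = st$m_low, n_low = st$n_low,
    rauc_high = st$rauc_high, rzauc_high = st$rzauc_high,
    rauc_low = st$rauc_low, rzauc_low = st$rzauc_low
  )
  class(out) <- c("restriction_scan", "data.frame")
  attr(out, "auc") <- st$auc
  attr(out, "m") <- st$m
  attr(out, "n") <- st$n
  out
}

#' Optimal restriction of a scanned biomarker
#'
#' Picks the candidate restriction and part (high/low) with the largest
#' absolute rzAUC from a [scan_restrictions()] result. Ties are broken in
#' favour of the candidate retaining more samples, then the smaller
#' restriction value. The informative range is `(-Inf, r]` for the low part
#' and `(r, Inf)` for the high part.
#'
#' @param scan a `restriction_scan` data frame.
#' @return a list with `r_opt`, `part_opt`, `rauc_opt`, `rzauc_opt`,
#'   `fpr_opt`, `tpr_opt`, `n_kept` and `informative_range` (length-2
#'   numeric, open below/above per part).
#' @export
optimal_restriction <- function(scan) {
  stopifnot(inherits(scan, "restriction_scan"))
  if (all(is.na(scan$rzauc_high)) && all(is.na(scan$rzauc_low))) {
    stop("no computable restriction candidate in scan")
  }
  prep <- list(r = scan$r)
  st <- list(m = attr(scan, "m"), n = attr(scan, "n"),
             fpr = scan$fpr, tpr = scan$tpr,
             m_high = scan$m_high, n_high = scan$n_high,
             rauc_high = scan$rauc_high, rauc_low = scan$rauc_low,
             rzauc_high = scan$rzauc_high, rzauc_low = scan$rzauc_low)
  opt <- scan_opt(prep, st)
  opt$informative_range <- informative_range(opt$r_opt, opt$part_opt)
  opt
}

informative_range <- function(r, part) {
  if (part == "low") c(-Inf, r) else c(r, Inf)
}

in_informative_range <- function(values, range, part) {
  if (part == "low") values <= range[2L] else values > range[1L]
}
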