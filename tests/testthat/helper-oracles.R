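# Independent brute-force oracles, deliberately naive: quadratic pair
# counting and exhaustive enumeration over all (restriction, part) pairs.

pair_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# rAUC of one side by explicit subsetting, NA when the side is degenerate
subset_rauc <- function(values, labels, r, part) {
  keep <- if (part == "high") values > r else values <= r
  v <- values[keep]
  d <- labels[keep]
  if (sum(d == 1) < 1 || sum(d == 0) < 1) return(NA_real_)
  pair_auc(v, d)
}

subset_rzauc <- function(values, labels, r, part) {
  keep <- if (part == "high") values > r else values <= r
  m <- sum(labels[keep] == 1)
  n <- sum(labels[keep] == 0)
  ra <- subset_rauc(values, labels, r, part)
  (ra - 0.5) / sqrt((m + n + 1) / (12 * m * n))
}

# exhaustive maximiser of |rzAUC| over every candidate and both parts
brute_force_opt <- function(values, labels) {
  best <- -Inf
  for (r in c(sort(unique(values)), -Inf)) {
    for (part in c("high", "low")) {
      rz <- subset_rzauc(values, labels, r, part)
      if (!is.na(rz) && abs(rz) > best) best <- abs(rz)
    }
  }
  best
}

# small random instance with ties (integer-valued biomarker)
random_small_dataset <- function(max_n = 12L) {
  n <- sample(2:(max_n %/% 2), 1L)
  m <- sample(2:(max_n %/% 2), 1L)
  list(values = sample.int(8L, n + m, replace = TRUE) +
         round(stats::runif(n + m), 2),
       labels = rep(c(0L, 1L), c(n, m)))
}
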