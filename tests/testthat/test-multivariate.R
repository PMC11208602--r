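test_that("gate-count filtering applies the detection rule verbatim", {
  counts <- cbind(allzero = rep(0L, 10),
                  one_detect = c(11L, rep(0L, 9)),
                  borderline = c(rep(10L, 10)))
  expect_equal(filter_features(counts, 0.1, 10L),
               "one_detect") # 1/10 >= 10%; counts of exactly 10 not > 10
  expect_equal(filter_features(counts, 0, 10L), colnames(counts))
  expect_error(filter_features(cbind(a = -1L)), "nonnegative")
})

test_that("sentinel encoding substitutes exactly the out-of-range entries", {
  x <- cbind(f1 = c(1, 5, 9), f2 = c(2, 4, 6))
  map <- structure(list(features = c("f1", "f2"),
                        range_lo = c(f1 = 4, f2 = -Inf),
                        range_hi = c(f1 = Inf, f2 = Inf),
                        part = c(f1 = "high", f2 = "high"),
                        sentinel = -1), class = "restriction_map")
  out <- restrict_transform(x, map)
  expect_equal(out[, "f1"], c(-1, 5, 9), ignore_attr = TRUE)
  # keep-all column untouched
  expect_equal(out[, "f2"], x[, "f2"])
  # idempotence and conservation
  expect_equal(restrict_transform(out, map), out)
  expect_equal(sum(out[, "f1"] == -1), sum(!(x[, "f1"] > 4)))

  # sentinel must undercut every in-range value
  bad <- map
  bad$sentinel <- 5
  expect_error(restrict_transform(x, bad), "not strictly below")
  auto <- map
  auto$sentinel <- NULL
  expect_warning(out2 <- restrict_transform(x, auto), "auto-selected")
  expect_equal(unname(out2[1, "f1"]), min(5, 9) - 1)
})

test_that("restriction maps reproduce the per-feature univariate fits", {
  set.seed(121)
  x <- cbind(a = c(rnorm(40, 5), rnorm(40, 6, 2)),
             b = rnorm(80, 5))
  y <- rep(0:1, each = 40)
  map <- fit_restriction_map(x, y)
  for (ft in c("a", "b")) {
    fit <- rroc(x[, ft], y, n_permutations = 0)
    expect_equal(unname(map$range_lo[ft]), fit$informative_range[1])
    expect_equal(unname(map$range_hi[ft]), fit$informative_range[2])
    expect_equal(unname(map$part[ft]), fit$part_opt)
  }
})

make_forest_data <- function(n, seed) {
  set.seed(seed)
  cls <- rep(0:1, each = n / 2)
  x <- cbind(signal = ifelse(cls == 1, rnorm(n, 8), rnorm(n, 4)),
             noise1 = rnorm(n, 5), noise2 = rnorm(n, 5))
  list(x = x, y = cls)
}

test_that("forests are seed-reproducible and learn a separating feature", {
  d <- make_forest_data(60, 131)
  cfg <- forest_config(n_trees = 100, seed = 3)
  f1 <- rroc_forest(d$x, d$y, config = cfg)
  f2 <- rroc_forest(d$x, d$y, config = cfg)
  expect_identical(predict(f1, d$x, type = "prob"),
                   predict(f2, d$x, type = "prob"))
  # perfectly separating feature: training CCR 1
  cm <- confusion_metrics(predict(f1, d$x), d$y)
  expect_equal(cm$ccr, 1)
})

test_that("an all-keep restriction map leaves the forest pipeline unchanged", {
  d <- make_forest_data(60, 141)
  keep_all <- structure(list(features = colnames(d$x),
                             range_lo = stats::setNames(rep(-Inf, 3), colnames(d$x)),
                             range_hi = stats::setNames(rep(Inf, 3), colnames(d$x)),
                             part = stats::setNames(rep("high", 3), colnames(d$x)),
                             sentinel = -1), class = "restriction_map")
  expect_equal(restrict_transform(d$x, keep_all), d$x)
  cfg <- forest_config(n_trees = 100, seed = 5)
  f_r <- rroc_forest(d$x, d$y, map = keep_all, config = cfg)
  f_u <- rroc_forest(d$x, d$y, config = cfg)
  expect_identical(predict(f_r, d$x, type = "prob"),
                   predict(f_u, d$x, type = "prob"))
})

test_that("restriction maps fitted on training data transfer verbatim to validation", {
  d_tr <- make_forest_data(60, 151)
  d_va <- make_forest_data(60, 152)
  map <- fit_restriction_map(d_tr$x, d_tr$y)
  f <- rroc_forest(d_tr$x, d_tr$y, map = map,
                   config = forest_config(n_trees = 100, seed = 1))
  # the model's stored map is the training map, not refit on newdata
  expect_identical(f$map, map)
  manual <- restrict_transform(d_va$x, map)
  expect_identical(predict(f, d_va$x, type = "prob"),
                   predict(f, manual, type = "prob"))
})

test_that("forests trained on permuted labels predict at the no-information rate", {
  set.seed(161)
  n_tr <- 80
  n_te <- 300
  x_tr <- matrix(rnorm(n_tr * 5, 5), n_tr, 5,
                 dimnames = list(NULL, paste0("f", 1:5)))
  x_te <- matrix(rnorm(n_te * 5, 5), n_te, 5,
                 dimnames = list(NULL, paste0("f", 1:5)))
  y_tr <- sample(rep(0:1, each = n_tr / 2))
  y_te <- rep(0:1, each = n_te / 2)
  f <- rroc_forest(x_tr, y_tr, config = forest_config(n_trees = 200, seed = 9))
  ccr <- confusion_metrics(predict(f, x_te), y_te)$ccr
  expect_lt(abs(ccr - 0.5), 0.1)
})
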