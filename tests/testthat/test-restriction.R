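test_that("restricted AUC equals the plain AUC on the explicitly restricted subset", {
  set.seed(51)
  for (i in 1:80) {
    d <- random_small_dataset()
    for (r in c(sort(unique(d$values)), -Inf)) {
      for (part in c("high", "low")) {
        expected <- subset_rauc(d$values, d$labels, r, part)
        if (is.na(expected)) {
          expect_error(rauc(d$values, d$labels, r, part), "unrestrictable")
        } else {
          expect_equal(rauc(d$values, d$labels, r, part), expected,
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("restricting below the minimum keeps the full dataset", {
  v <- c(1, 2, 5, 6, 3, 4, 7, 8)
  d <- rep(0:1, each = 4)
  expect_equal(rauc(v, d, min(v) - 1, "high"), auc(roc_curve(v, d)))
  # r = 4.5 high keeps neg {5,6} vs pos {7,8}: perfectly separated
  expect_equal(suppressWarnings(rauc(v, d, 4.5, "high")), 1.0)
})

test_that("rzAUC implements the null-variance standardisation", {
  # m = n = 10 at rAUC 0.75: 0.25 / sqrt(21/1200)
  v <- c(sort(rnorm(10)), sort(rnorm(10)))
  # construct exact rAUC 0.75 instead via direct formula check on a
  # dataset whose full AUC is 0.75: 10 vs 10 with 75 of 100 pairs won
  v <- c(1:10, 3.5 + 1:10 * 0.9)
  d <- rep(0:1, each = 10)
  ra <- pair_auc(v, d)
  rz <- rzauc(v, d, min(v) - 1, "high")
  expect_equal(rz, (ra - 0.5) / sqrt((10 + 10 + 1) / (12 * 100)))
  # the reference case: rAUC 0.75 with 10 + 10 samples
  expect_equal((0.75 - 0.5) / sqrt((21) / 1200), 1.889822, tolerance = 1e-6)

  # rAUC exactly 0.5 gives rzAUC 0 (classes share the same tied values)
  expect_equal(rzauc(rep(c(1, 2), 6), rep(c(0, 0, 1, 1), 3), 3, "low"), 0)

  # doubling both side counts at fixed rAUC strictly increases |rzAUC|
  expect_gt(abs((0.75 - 0.5) / sqrt(rocrestrict:::rzauc_null_var(20, 20))),
            abs((0.75 - 0.5) / sqrt(rocrestrict:::rzauc_null_var(10, 10))))

  # small sides trigger the accuracy warning
  expect_warning(rzauc(c(1, 2, 3, 4), c(0, 1, 0, 1), 0, "high"),
                 "fewer than 6")
})

test_that("the scan reproduces per-candidate subset recomputation and conserves counts", {
  set.seed(61)
  for (i in 1:40) {
    d <- random_small_dataset()
    sc <- scan_restrictions(d$values, d$labels)
    m <- sum(d$labels)
    n <- length(d$labels) - m
    expect_true(all(sc$m_high + sc$m_low == m))
    expect_true(all(sc$n_high + sc$n_low == n))
    expect_true(-Inf %in% sc$r)
    expect_equal(nrow(sc), length(unique(d$values)) + 1L)
    for (j in seq_len(nrow(sc))) {
      eh <- subset_rauc(d$values, d$labels, sc$r[j], "high")
      el <- subset_rauc(d$values, d$labels, sc$r[j], "low")
      expect_equal(sc$rauc_high[j], eh, tolerance = 1e-10)
      expect_equal(sc$rauc_low[j], el, tolerance = 1e-10)
    }
  }
})

test_that("the selected optimum matches the exhaustive brute-force maximiser", {
  set.seed(71)
  for (i in 1:60) {
    d <- random_small_dataset()
    opt <- optimal_restriction(scan_restrictions(d$values, d$labels))
    expect_equal(abs(opt$rzauc_opt), brute_force_opt(d$values, d$labels),
                 tolerance = 1e-9)
  }
})

test_that("argmax ties resolve to more samples kept, then the smaller restriction", {
  # perfect separation: keep-all as high part (r = -Inf) ties with
  # keep-all as low part (r = max); the smaller candidate must win
  opt <- optimal_restriction(scan_restrictions(c(1, 2, 3, 4), c(0, 0, 1, 1)))
  expect_equal(opt$r_opt, -Inf)
  expect_equal(opt$part_opt, "high")
  expect_equal(opt$n_kept, 4)
  expect_equal(opt$rauc_opt, 1)
  expect_equal(opt$informative_range, c(-Inf, Inf))
})

test_that("relabelling the classes mirrors the rzAUC curves and keeps the optimum", {
  set.seed(81)
  for (i in 1:25) {
    d <- random_small_dataset()
    sc1 <- scan_restrictions(d$values, d$labels)
    sc2 <- scan_restrictions(d$values, 1L - d$labels)
    expect_equal(sc1$r, sc2$r)
    expect_equal(sc2$rzauc_high, -sc1$rzauc_high, tolerance = 1e-9)
    expect_equal(sc2$rzauc_low, -sc1$rzauc_low, tolerance = 1e-9)
    o1 <- optimal_restriction(sc1)
    o2 <- optimal_restriction(sc2)
    expect_equal(o1$r_opt, o2$r_opt)
    expect_equal(o1$rzauc_opt, -o2$rzauc_opt, tolerance = 1e-9)
  }
})

test_that("a symmetric equal-variance pair keeps essentially all samples", {
  sc <- two_class_scenarios()$overlap_equal_var
  kept <- vapply(1:10, function(s) {
    d <- simulate_two_class(sc, seed = s)
    rroc(d$value, d$class, n_permutations = 0)$n_kept
  }, 0)
  expect_gte(stats::median(kept), 0.9 * 200)
})
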