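test_that("channel preprocessing applies the asinh transform and landmark rescale", {
  raw <- cbind(ch = c(0, 1000, 2000))
  out <- preprocess_channels(raw, c(ch = 1000), landmarks = list(ch = c(0, 1)))
  # landmarks 0/1 make the rescale the identity on the asinh scale
  expect_equal(unname(out[2, "ch"]), asinh(1))
  expect_equal(round(unname(out[2, "ch"]), 5), 0.88137)
  expect_equal(unname(out[1, "ch"]), 0)

  out2 <- preprocess_channels(raw, c(ch = 1000),
                              landmarks = list(ch = c(0.2, 1.2)))
  # MFI- maps to 0, MFI+ maps to 1
  expect_equal(out2[, "ch"], (asinh(raw[, "ch"] / 1000) - 0.2) / 1,
               ignore_attr = TRUE)
  expect_error(preprocess_channels(raw, c(ch = 1000),
                                   landmarks = list(ch = c(1, 1))),
               "zero landmark spread")
  expect_error(preprocess_channels(raw, c(other = 1)), "missing asinh cofactor")
})

test_that("estimated MFI landmarks recover a clearly bimodal channel", {
  set.seed(171)
  x <- c(rnorm(600, 0, 0.1), rnorm(400, 1, 0.1))
  lm <- find_mfi_landmarks(x)
  expect_lt(abs(lm[1] - 0), 0.05)
  expect_lt(abs(lm[2] - 1), 0.05)
})

test_that("zero adjustment adds the global pseudo-proportion and renormalises", {
  adj <- zero_adjust_proportions(matrix(c(0.5, 0.5, 0), 1))
  # smallest positive proportion 0.5 -> pseudo 5e-4
  expect_equal(as.vector(adj), c(0.5005, 0.5005, 0.0005) / 1.0015)
  expect_equal(rowSums(adj), 1)
  expect_error(zero_adjust_proportions(matrix(c(1.2, 0.2), 1)), "sum to 1")
})

test_that("the Dirichlet MLE recovers generating parameters and caps degeneracy", {
  set.seed(181)
  a0 <- c(2, 3, 5)
  p <- t(replicate(5000, {
    g <- rgamma(3, a0)
    g / sum(g)
  }))
  a_hat <- estimate_dirichlet(p)
  expect_true(all(abs(a_hat - a0) / a0 < 0.10))

  # identical rows: precision diverges and is capped with a warning
  same <- matrix(c(0.2, 0.3, 0.5), 50, 3, byrow = TRUE)
  expect_warning(a_cap <- estimate_dirichlet(same), "capped")
  expect_equal(sum(a_cap), 1e6, tolerance = 1e-6)
})

test_that("leaf Gaussian estimation pools cells and drops singleton leaves", {
  cells <- matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE)
  gs <- estimate_leaf_gaussians(cells, c("L", "L"))
  expect_equal(unname(gs$mu$L), c(1, 1))
  expect_equal(unname(gs$sigma$L), matrix(2, 2, 2))

  cells3 <- rbind(cells, c(9, 9))
  expect_warning(gs2 <- estimate_leaf_gaussians(cells3, c("L", "L", "solo")),
                 "fewer than 2 cells: solo")
  expect_named(gs2$mu, "L")

  set.seed(191)
  mu0 <- c(1, 2, 3)
  sg0 <- diag(3) * 0.5 + 0.1
  big <- MASS::mvrnorm(1e5, mu0, sg0)
  gs3 <- estimate_leaf_gaussians(big, rep("A", 1e5))
  expect_lt(max(abs(gs3$mu$A - mu0)), 0.02)
  expect_lt(max(abs(gs3$sigma$A - sg0)), 0.02)
})

test_that("effect injection hits the target mean exactly and conserves precision", {
  tr <- example_gating_tree()
  s <- sum(tr$alpha)

  tr2 <- adjust_effect(tr, "CD8_TEMRA", 0.3323)
  expect_equal(sum(tr2$alpha), s, tolerance = 1e-12)
  expect_equal(node_alpha(tr2)[["CD8_TEMRA"]] / sum(tr2$alpha), 0.3323,
               tolerance = 1e-12)

  # three-leaf worked case via an explicit leaf subset on a small tree
  small <- gating_tree(
    channels = "x",
    nodes = list(root = list(parent = NA),
                 A = list(parent = "root", gate = list(x = c(-Inf, 1))),
                 B = list(parent = "root", gate = list(x = c(1, 2))),
                 C = list(parent = "root", gate = list(x = c(2, Inf)))),
    alpha = c(A = 2, B = 3, C = 5),
    mu = list(A = 0, B = 1.5, C = 3),
    sigma = list(A = matrix(0.01), B = matrix(0.01), C = matrix(0.01)))
  adj <- adjust_effect(small, "C", 0.8)
  expect_equal(unname(adj$alpha[c("A", "B", "C")]), c(0.8, 1.2, 8))
  expect_equal(sum(adj$alpha), 10)

  # fixed point: targeting the current mean changes nothing
  fp <- adjust_effect(small, "C", 0.5)
  expect_equal(fp$alpha, small$alpha)
  # every other population shifts whenever t differs from the prior mean
  expect_false(any(adj$alpha[c("A", "B")] == small$alpha[c("A", "B")]))

  expect_error(adjust_effect(small, "C", 1), "strictly in")
  expect_error(adjust_effect(small, c("A", "B", "C"), 0.5), "proper subset")
  # targeting an intermediate node scales its leaves proportionally
  trn <- adjust_effect(tr, "CD4", 0.6)
  ratio <- trn$alpha[leaves_under(tr, "CD4")] /
    tr$alpha[leaves_under(tr, "CD4")]
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
})

test_that("setting a node's Dirichlet parameter changes only that subtree", {
  tr <- example_gating_tree()
  tr2 <- set_dirichlet_parameter(tr, "CD4_TEM", 10.7)
  expect_equal(tr2$alpha[["CD4_TEM"]], 10.7)
  others <- setdiff(tree_leaves(tr), "CD4_TEM")
  expect_equal(tr2$alpha[others], tr$alpha[others])
})

test_that("simulated samples conserve cell counts and long-run proportions", {
  tr <- example_gating_tree()
  sm <- simulate_cells(tr, 1234, seed = 201)
  expect_equal(nrow(sm$cells), 1234)
  expect_equal(length(sm$population), 1234)

  set.seed(211)
  props <- t(replicate(1000, {
    s <- simulate_cells(tr, 200)
    as.vector(table(s$population)) / 200
  }))
  mean_p <- colMeans(props)
  se <- apply(props, 2, sd) / sqrt(1000)
  expect_true(all(abs(mean_p - tr$alpha / sum(tr$alpha)) < 3 * se + 1e-3))

  # one-leaf tree: all cells from the single Gaussian
  one <- gating_tree(
    channels = "x",
    nodes = list(root = list(parent = NA),
                 only = list(parent = "root", gate = list(x = c(-Inf, Inf)))),
    alpha = c(only = 3), mu = list(only = 5),
    sigma = list(only = matrix(0.04)))
  so <- simulate_cells(one, 500, seed = 221)
  expect_true(all(so$population == "only"))
  expect_lt(abs(mean(so$cells) - 5), 0.05)
})

test_that("gating recovers generating populations and conserves node counts", {
  tr <- example_gating_tree()
  sm <- simulate_cells(tr, 4000, seed = 231)
  pops <- assign_populations(sm$cells, tr)
  # >= 6 sigma separation: every cell returns to its generating leaf
  expect_equal(as.vector(table(pops)), as.vector(table(sm$population)))
  counts <- apply_gating(sm$cells, tr)
  expect_equal(unname(counts["Tcells"]), 4000)
  expect_equal(unname(counts["CD4"] + counts["CD8"]), 4000)
  lv <- tree_leaves(tr)
  expect_equal(sum(counts[lv]), 4000)

  # empty matrix gives all-zero counts
  empty <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, tr$channels))
  expect_true(all(apply_gating(empty, tr) == 0))

  # a tree whose gates do not tile the space raises a coverage error
  gap <- gating_tree(
    channels = "x",
    nodes = list(root = list(parent = NA),
                 box = list(parent = "root", gate = list(x = c(0, 1)))),
    alpha = c(box = 1), mu = list(box = 0.5),
    sigma = list(box = matrix(0.01)))
  expect_error(assign_populations(cbind(x = c(0.5, 2)), gap),
               "gating-coverage")
})

test_that("the generative model is recoverable from simulated cohorts", {
  tr <- example_gating_tree()
  set.seed(241)
  cohort <- lapply(1:100, function(i) simulate_cells(tr, 400)$cells)
  refit <- suppressWarnings(fit_gating_model(cohort, tr))
  expect_true(all(abs(refit$alpha - tr$alpha) / tr$alpha < 0.35))
  expect_lt(abs(sum(refit$alpha) - sum(tr$alpha)) / sum(tr$alpha), 0.3)
  expect_lt(max(abs(refit$mu[["CD4_TEM"]] - tr$mu[["CD4_TEM"]])), 0.01)
})

test_that("gating trees survive a JSON round trip", {
  tr <- example_gating_tree()
  path <- withr::local_tempfile(fileext = ".json")
  write_gating_tree(tr, path)
  tr2 <- read_gating_tree(path)
  expect_equal(tr2$alpha, tr$alpha)
  expect_equal(tr2$mu, tr$mu)
  expect_equal(tr2$sigma, tr$sigma)
  expect_identical(tree_leaves(tr2), tree_leaves(tr))
  # and the shipped fixture matches the in-code constructor
  shipped <- read_gating_tree(system.file("extdata",
                                          "tcell_tree_synthetic.json",
                                          package = "rocrestrict"))
  expect_equal(shipped$alpha, tr$alpha)
})
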