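#' Simulate cells from a gating tree
#'
#' Draws one synthetic flow cytometry sample from the generative model: a
#' proportion vector p ~ Dirichlet(alpha) over the leaf populations, an
#' integer allocation of `n_cells * p` cells per leaf (largest-remainder
#' rounding, so the counts always sum to `n_cells`), and multivariate
#' Gaussian antigen values per leaf. A covariance matrix that is not
#' positive definite is ridged by `1e-8 * trace / m` before sampling (with
#' a message).
#'
#' @param tree a [gating_tree()] with `alpha`, `mu`, `sigma` on every leaf.
#' @param n_cells number of cells to draw (>= 1).
#' @param seed optional integer seed.
#' @return a list with `cells` (matrix `n_cells` x channels) and
#'   `population` (factor of generating leaves).
#' @export
simulate_cells <- function(tree, n_cells, seed = NULL) {
  stopifnot(inherits(tree, "gating_tree"))
  if (n_cells < 1L) stop("n_cells must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  lv <- tree_leaves(tree)
  p <- rdirichlet_(tree$alpha)
  counts <- largest_remainder(n_cells * p)
  m <- length(tree$channels)
  cells <- matrix(NA_real_, n_cells, m,
                  dimnames = list(NULL, tree$channels))
  pop <- character(n_cells)
  at <- 0L
  for (j in seq_along(lv)) {
    ck <- counts[j]
    if (ck == 0L) next
    sg <- tree$sigma[[lv[j]]]
    ok <- tryCatch({chol(sg); TRUE}, error = function(e) FALSE)
    if (!ok) {
      sg <- sg + diag(1e-8 * sum(diag(sg)) / m, m)
      message("ridged singular covariance of leaf ", lv[j])
    }
    cells[at + seq_len(ck), ] <- MASS::mvrnorm(ck, tree$mu[[lv[j]]], sg)
    pop[at + seq_len(ck)] <- lv[j]
    at <- at + ck
  }
  list(cells = cells, population = factor(pop, levels = lv))
}

#' @rdname simulate_cells
#' @param object a [gating_tree()] (generic-conforming name).
#' @param nsim number of samples to draw.
#' @param ... unused.
#' @return `simulate.gating_tree()` returns a list of `nsim` samples.
#' @export
simulate.gating_tree <- function(object, nsim = 1, seed = NULL,
                                 n_cells = 10000L, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) simulate_cells(object, n_cells))
}

rdirichlet_ <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # guard against underflow
  g / sum(g)
}

# integer allocation summing exactly to round(sum(x))
largest_remainder <- function(x) {
  total <- round(sum(x))
  base <- floor(x)
  short <- total - sum(base)
  if (short > 0L) {
    frac <- x - base
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

#' Inject a disease effect into a gating tree
#'
#' Adjusts the Dirichlet parameters so a chosen subset of leaf populations
#' A has target mean proportion t, while conserving the total precision
#' \eqn{s = \sum_k \alpha_k}: parameters in A are scaled by \eqn{t s / s_A}
#' and all others by \eqn{(1-t) s / s_{\bar A}}. Targeting an intermediate
#' node scales its descendant leaves proportionally, so every other node's
#' expected proportion shifts as well.
#'
#' @param tree a [gating_tree()].
#' @param population a node name (its descendant leaves form A) or an
#'   explicit character vector of leaf names.
#' @param t target mean proportion of A, strictly in (0, 1).
#' @return the adjusted [gating_tree()].
#' @examples
#' tr <- example_gating_tree()
#' tr2 <- adjust_effect(tr, "CD8_TEMRA", 0.3323)
#' node_alpha(tr2)[["CD8_TEMRA"]] / sum(tr2$alpha) # 0.3323
#' @export
adjust_effect <- function(tree, population, t) {
  stopifnot(inherits(tree, "gating_tree"))
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1) {
    stop("target mean proportion t must lie strictly in (0, 1)")
  }
  a_set <- resolve_leafset(tree, population)
  lv <- tree_leaves(tree)
  if (length(a_set) == length(lv)) {
    stop("the adjusted subset must be a proper subset of the leaves")
  }
  s <- sum(tree$alpha)
  s_a <- sum(tree$alpha[a_set])
  s_nota <- s - s_a
  alpha <- tree$alpha
  alpha[a_set] <- alpha[a_set] * t * s / s_a
  rest <- setdiff(lv, a_set)
  alpha[rest] <- alpha[rest] * (1 - t) * s / s_nota
  tree$alpha <- alpha
  tree
}

#' Set a node's Dirichlet parameter directly
#'
#' Rescales the descendant leaves of `population` so the node's Dirichlet
#' parameter equals `value`, leaving every other leaf parameter unchanged.
#' Unlike [adjust_effect()] this changes the total precision; it mirrors
#' introducing a disease association by setting a population's parameter to
#' a drawn biomarker value.
#'
#' @inheritParams adjust_effect
#' @param value the new Dirichlet parameter of the node (> 0).
#' @return the modified [gating_tree()].
#' @export
set_dirichlet_parameter <- function(tree, population, value) {
  stopifnot(inherits(tree, "gating_tree"))
  if (value <= 0) stop("the Dirichlet parameter must be positive")
  a_set <- resolve_leafset(tree, population)
  cur <- sum(tree$alpha[a_set])
  tree$alpha[a_set] <- tree$alpha[a_set] * value / cur
  tree
}

#' Maximum-likelihood Dirichlet estimation from proportions
#'
#' Estimates the Dirichlet parameter vector from a samples x populations
#' proportion matrix. Zero proportions are first adjusted by adding a
#' pseudo-proportion of `0.001` times the smallest positive proportion
#' observed anywhere in the matrix, then renormalising each row. The MLE
#' uses the standard fixed-point iteration
#' \eqn{\psi(\alpha_k) = \psi(\sum \alpha) + \overline{\log p_k}}, with a
#' method-of-moments initialisation.
#'
#' @param proportions numeric matrix, rows summing to 1, entries >= 0.
#' @param tol relative convergence tolerance (default 1e-7).
#' @param max_iter iteration cap (default 10000); non-convergence is an
#'   error with diagnostics.
#' @param precision_cap upper bound on the total precision; degenerate
#'   inputs (e.g. all rows identical) drive the precision upward without
#'   bound and are capped here with a warning (default 1e6).
#' @return named numeric vector of positive parameter estimates.
#' @examples
#' p <- matrix(c(0.2, 0.3, 0.5), 100, 3, byrow = TRUE) +
#'   matrix(rnorm(300, 0, 0.01), 100, 3)
#' p <- abs(p) / rowSums(abs(p))
#' estimate_dirichlet(p)
#' @export
estimate_dirichlet <- function(proportions, tol = 1e-7, max_iter = 10000L,
                               precision_cap = 1e6) {
  p <- zero_adjust_proportions(proportions)

  logp <- colMeans(log(p))
  mean_p <- colMeans(p)
  # method-of-moments precision from the first component
  e1 <- mean_p[1L]
  e2 <- mean(p[, 1L]^2)
  s0 <- (e1 - e2) / max(e2 - e1^2, .Machine$double.eps)
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  alpha <- mean_p * s0

  for (it in seq_len(max_iter)) {
    new_alpha <- inv_digamma(digamma(sum(alpha)) + logp)
    if (sum(new_alpha) > precision_cap) {
      warning("Dirichlet precision diverged (near-identical proportion ",
              "rows); capped at ", format(precision_cap))
      new_alpha <- new_alpha * precision_cap / sum(new_alpha)
      alpha <- new_alpha
      break
    }
    delta <- max(abs(new_alpha - alpha) / pmax(abs(alpha), 1e-12))
    alpha <- new_alpha
    if (delta < tol) break
    if (it == max_iter) {
      stop("Dirichlet MLE did not converge in ", max_iter,
           " iterations (last relative change ", format(delta), ")")
    }
  }
  if (!is.null(colnames(p))) names(alpha) <- colnames(p)
  alpha
}

#' Zero-adjust a proportion matrix for Dirichlet estimation
#'
#' Likelihood estimation cannot handle proportions equal to zero, so a
#' pseudo-proportion of `0.001` times the smallest positive proportion
#' observed anywhere in the matrix is added to every entry and each row is
#' renormalised to sum to 1.
#'
#' @param proportions numeric matrix, rows summing to 1, entries >= 0.
#' @return the adjusted, strictly positive proportion matrix.
#' @examples
#' zero_adjust_proportions(matrix(c(0.5, 0.5, 0), 1)) # pseudo = 5e-4
#' @export
zero_adjust_proportions <- function(proportions) {
  p <- as.matrix(proportions)
  if (any(p < 0)) stop("proportions must be nonnegative")
  if (any(abs(rowSums(p) - 1) > 1e-6)) stop("each row must sum to 1")
  pos <- p[p > 0]
  if (length(pos) == 0L) stop("all proportions are zero")
  p <- p + 0.001 * min(pos)
  p / rowSums(p)
}

# Newton inversion of the digamma function
inv_digamma <- function(y) {
  x <- ifelse(y >= -2.22, exp(y) + 0.5, -1 / (y - digamma(1)))
  for (i in 1:5) x <- x - (digamma(x) - y) / trigamma(x)
  x
}

#' Per-leaf Gaussian estimation from assigned cells
#'
#' Pools the cells assigned to each leaf population and estimates the
#' sample mean vector and (unbiased) covariance matrix. Leaves with fewer
#' than 2 cells have no estimable covariance and are removed with a
#' warning.
#'
#' @param cells numeric matrix, cells x channels.
#' @param populations factor/character of leaf assignments, one per cell.
#' @return a list with named lists `mu` and `sigma` over the retained
#'   leaves.
#' @export
estimate_leaf_gaussians <- function(cells, populations) {
  cells <- as.matrix(cells)
  populations <- as.factor(populations)
  stopifnot(nrow(cells) == length(populations))
  counts <- table(populations)
  drop <- names(counts)[counts < 2L]
  if (length(drop)) {
    warning("removed leaf population(s) with fewer than 2 cells: ",
            paste(drop, collapse = ", "))
  }
  keep <- setdiff(levels(populations), drop)
  mu <- list()
  sigma <- list()
  for (l in keep) {
    xi <- cells[populations == l, , drop = FALSE]
    mu[[l]] <- colMeans(xi)
    sigma[[l]] <- stats::cov(xi)
  }
  list(mu = mu, sigma = sigma)
}

#' Fit the generative model of a gating tree from cell samples
#'
#' Estimates all generative parameters of a gating tree from a list of
#' per-sample cell matrices: cells are gated, per-sample leaf proportions
#' feed the Dirichlet MLE ([estimate_dirichlet()]), and pooled cells per
#' leaf feed the Gaussian estimates ([estimate_leaf_gaussians()]). Leaves
#' whose Gaussian could not be estimated keep the tree's existing
#' parameters.
#'
#' @param samples list of cell matrices (cells x channels).
#' @param tree a [gating_tree()] providing the hierarchy and gates.
#' @param ... passed to [estimate_dirichlet()].
#' @return the tree with `alpha`, `mu`, `sigma` replaced by estimates.
#' @export
fit_gating_model <- function(samples, tree, ...) {
  stopifnot(inherits(tree, "gating_tree"), is.list(samples))
  lv <- tree_leaves(tree)
  props <- matrix(0, length(samples), length(lv),
                  dimnames = list(NULL, lv))
  all_cells <- vector("list", length(samples))
  all_pops <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    pops <- assign_populations(samples[[i]], tree)
    props[i, ] <- as.vector(table(pops)) / length(pops)
    all_cells[[i]] <- as_cell_matrix(samples[[i]], tree)
    all_pops[[i]] <- as.character(pops)
  }
  alpha <- estimate_dirichlet(props, ...)
  gs <- estimate_leaf_gaussians(do.call(rbind, all_cells),
                                factor(unlist(all_pops), levels = lv))
  tree$alpha[lv] <- alpha[lv]
  for (l in names(gs$mu)) {
    tree$mu[[l]] <- gs$mu[[l]]
    tree$sigma[[l]] <- gs$sigma[[l]]
  }
  tree
}

#' Preprocess raw cytometry channels
#'
#' The standard transform-and-rescale preprocessing: raw intensities are
#' inverse-hyperbolic-sine transformed with a per-channel cofactor,
#' \eqn{x \mapsto asinh(x / cofactor)}, and then min-max standardised per
#' channel using the median fluorescence intensity landmarks of the
#' negative and positive cell populations,
#' \eqn{x \mapsto (x - MFI^-)/(MFI^+ - MFI^-)}, so the rescaled landmarks
#' sit at 0 and 1. Landmarks may be supplied or are otherwise estimated
#' per channel from a two-component Gaussian mixture (component medians).
#'
#' @param raw numeric matrix, cells x channels, named columns.
#' @param cofactors named numeric vector covering every channel (values
#'   > 0).
#' @param landmarks optional named list of `c(neg, pos)` landmark pairs on
#'   the asinh scale; estimated when missing. Equal landmarks are an
#'   error.
#' @return matrix of rescaled intensities with attribute `"landmarks"`.
#' @export
preprocess_channels <- function(raw, cofactors, landmarks = NULL) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw))) stop("raw cell matrix must have named columns")
  chans <- colnames(raw)
  missing_cf <- setdiff(chans, names(cofactors))
  if (length(missing_cf)) {
    stop("missing asinh cofactor for channel(s): ",
         paste(missing_cf, collapse = ", "))
  }
  if (any(cofactors[chans] <= 0)) stop("cofactors must be positive")
  out <- raw
  used <- list()
  for (ch in chans) {
    x <- asinh(raw[, ch] / cofactors[[ch]])
    lm <- if (!is.null(landmarks) && ch %in% names(landmarks)) {
      landmarks[[ch]]
    } else {
      find_mfi_landmarks(x)
    }
    if (lm[2L] == lm[1L]) {
      stop("zero landmark spread (MFI+ == MFI-) on channel ", ch)
    }
    out[, ch] <- (x - lm[1L]) / (lm[2L] - lm[1L])
    used[[ch]] <- c(neg = unname(lm[1L]), pos = unname(lm[2L]))
  }
  attr(out, "landmarks") <- used
  out
}

#' Estimate negative/positive MFI landmarks of one channel
#'
#' Fits a two-component univariate Gaussian mixture to the transformed
#' intensities and returns the medians of the two classified components,
#' ordered as (negative, positive).
#'
#' @param x numeric vector of transformed intensities.
#' @return numeric `c(neg, pos)`.
#' @importFrom mclust Mclust mclustBIC
#' @export
find_mfi_landmarks <- function(x) {
  fit <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  meds <- tapply(x, fit$classification, stats::median)
  sort(unname(meds))
}
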