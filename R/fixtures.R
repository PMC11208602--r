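#' Two-class Gaussian mixture specification
#'
#' Describes a two-class biomarker scenario: each class is a finite mixture
#' of normal components. Used by [simulate_two_class()] and by the closed
#' form [gaussian_mixture_auc()].
#'
#' @param neg,pos data frames with columns `weight`, `mean`, `sd`
#'   (component weights must sum to 1, scales positive).
#' @param n_neg,n_pos class sample sizes (>= 1).
#' @param scale `"sd"` (default) or `"variance"` interpretation of `sd`.
#' @return an object of class `two_class_spec`.
#' @export
two_class_spec <- function(neg, pos, n_neg, n_pos, scale = c("sd", "variance")) {
  scale <- match.arg(scale)
  check_mixture(neg)
  check_mixture(pos)
  stopifnot(n_neg >= 1L, n_pos >= 1L)
  structure(list(neg = neg, pos = pos, n_neg = as.integer(n_neg),
                 n_pos = as.integer(n_pos), scale = scale),
            class = "two_class_spec")
}

mixture_component <- function(weight, mean, sd) {
  data.frame(weight = weight, mean = mean, sd = sd)
}

#' Draw a labelled two-class dataset
#'
#' Samples `n_neg` negative and `n_pos` positive biomarker values from the
#' class mixtures of a [two_class_spec()]. Reproducible under `seed`.
#'
#' @param spec a `two_class_spec`.
#' @param seed optional integer seed.
#' @return a data frame with columns `value` and `class` (0 = negative,
#'   1 = positive).
#' @export
simulate_two_class <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "two_class_spec"))
  if (!is.null(seed)) set.seed(seed)
  draw <- function(comp, n) {
    k <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
    sds <- if (spec$scale == "sd") comp$sd else sqrt(comp$sd)
    stats::rnorm(n, comp$mean[k], sds[k])
  }
  data.frame(
    value = c(draw(spec$neg, spec$n_neg), draw(spec$pos, spec$n_pos)),
    class = rep(0:1, c(spec$n_neg, spec$n_pos))
  )
}

#' Canonical two-class simulation scenarios
#'
#' Named [two_class_spec()] presets covering the package's reference
#' designs: single-Gaussian pairs with equal or unequal dispersion, bimodal
#' positive classes, and a large 2500 + 2500 mixture whose optimum keeps an
#' elevated high part with a restricted AUC around 0.69. The `pct_*`
#' scenarios express the biomarker
#' in cell-population percentage units for use with the cytometry
#' simulator.
#'
#' @return a named list of `two_class_spec` objects.
#' @export
two_class_scenarios <- function() {
  g <- function(mean, sd) mixture_component(1, mean, sd)
  list(
    # perfectly separated / overlapping / uninformative / skewed designs
    perfect = two_class_spec(g(5, 1), g(15, 1), 100, 100),
    overlap_equal_var = two_class_spec(g(5, 1), g(6, 1), 100, 100),
    uninformative = two_class_spec(g(5, 1), g(5, 1), 100, 100),
    right_skew = two_class_spec(g(5, 1), g(6, 2), 100, 100),
    left_skew = two_class_spec(g(5, 2), g(6, 1), 100, 100),
    bimodal_pos = two_class_spec(
      g(5, 1),
      mixture_component(c(0.9, 0.1), c(5, 9), c(1, 1)), 100, 100),
    # large mixture: 20% of positives / 2% of negatives elevated
    large_mixture = two_class_spec(
      mixture_component(c(0.98, 0.02), c(6, 9), c(1, 1)),
      mixture_component(c(0.80, 0.20), c(6, 9), c(1, 1)),
      2500, 2500),
    # percentage-unit designs for the cytometry scenarios
    pct_symmetric = two_class_spec(g(7.7, 1), g(10.7, 1), 100, 100),
    pct_right_skew = two_class_spec(g(7.7, 1), g(8.7, 3), 100, 100),
    pct_left_skew = two_class_spec(g(7.7, 3), g(8.7, 1), 100, 100),
    pct_bimodal = two_class_spec(
      g(7.7, 1),
      mixture_component(c(0.8, 0.2), c(7.7, 16.7), c(1, 1)), 100, 100)
  )
}

#' Simulate a labelled flow cytometry cohort with a disease effect
#'
#' Generates per-sample synthetic flow cytometry data in which a disease
#' effect acts on one gating-tree population. For each sample a target
#' biomarker value is drawn from its class distribution; the tree's
#' Dirichlet parameters are adjusted accordingly; cells are simulated,
#' gated, and all population frequencies (percent of all cells) are
#' extracted as the feature matrix.
#'
#' Two effect modes are supported. `"dirichlet"` sets the target node's
#' Dirichlet parameter to the drawn value (leaf parameters scaled
#' proportionally; other nodes untouched, so precision changes with the
#' draw). `"target_mean"` treats the drawn value as the target mean
#' percentage and applies the precision-preserving adjustment
#' [adjust_effect()].
#'
#' @param tree a [gating_tree()] with Dirichlet and Gaussian parameters.
#' @param population name of the node or leaf carrying the effect.
#' @param spec_neg,spec_pos per-class distributions of the target value, as
#'   `weight`/`mean`/`sd` data frames (values in percent-like units, i.e.
#'   Dirichlet-parameter units when the tree precision is 100).
#' @param n_neg,n_pos samples per class.
#' @param cells_per_sample cells drawn per sample.
#' @param mode `"dirichlet"` (default) or `"target_mean"`.
#' @param seed optional integer seed.
#' @return a list with `features` (samples x populations matrix of
#'   percentages), `class` (0/1), and `target` (the drawn per-sample
#'   values).
#' @export
simulate_cytometry_scenario <- function(tree, population, spec_neg, spec_pos,
                                        n_neg = 100L, n_pos = 100L,
                                        cells_per_sample = 10000L,
                                        mode = c("dirichlet", "target_mean"),
                                        seed = NULL) {
  mode <- match.arg(mode)
  check_mixture(spec_neg)
  check_mixture(spec_pos)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(comp, n) {
    k <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
    stats::rnorm(n, comp$mean[k], comp$sd[k])
  }
  target <- c(draw(spec_neg, n_neg), draw(spec_pos, n_pos))
  cls <- rep(0:1, c(n_neg, n_pos))
  if (any(target <= 0 | target >= 100)) {
    stop("drawn target values must lie in (0, 100); ",
         "narrow the class distributions")
  }
  rows <- vector("list", length(target))
  for (i in seq_along(target)) {
    tr_i <- if (mode == "dirichlet") {
      set_dirichlet_parameter(tree, population, target[i])
    } else {
      adjust_effect(tree, population, target[i] / 100)
    }
    sm <- simulate_cells(tr_i, cells_per_sample)
    counts <- apply_gating(sm$cells, tr_i)
    rows[[i]] <- 100 * counts / cells_per_sample
  }
  features <- do.call(rbind, rows)
  rownames(features) <- sprintf("sample_%03d", seq_along(target))
  list(features = features, class = cls, target = target)
}
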