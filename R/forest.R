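#' Filter gate-count features by detection prevalence
#'
#' Keeps a gate feature when at least `min_fraction` of samples have more
#' than `min_count` cells in that gate.
#'
#' @param counts integer matrix/data frame, samples x gates, entries >= 0.
#' @param min_fraction minimum fraction of samples (default 0.1).
#' @param min_count count a sample must exceed to be counted as detected
#'   (default 10).
#' @return character vector of retained feature names.
#' @export
filter_features <- function(counts, min_fraction = 0.1, min_count = 10L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  detected <- colSums(counts > min_count)
  keep <- detected >= min_fraction * nrow(counts)
  colnames(counts)[keep]
}

#' Fit per-biomarker restriction maps on training data
#'
#' Runs the restriction scan ([rroc()] without permutations) on every
#' feature column and records its informative range, for use in
#' [restrict_transform()]. Fitting uses training data only; apply the
#' resulting map verbatim to validation data.
#'
#' @param x numeric matrix/data frame, samples x features.
#' @param labels binary labels.
#' @param sentinel replacement value for out-of-range entries (default -1,
#'   presuming strictly positive features such as proportions or counts).
#' @return an object of class `restriction_map`: per-feature
#'   `range_lo`/`range_hi`/`part` and the sentinel.
#' @export
fit_restriction_map <- function(x, labels, sentinel = -1) {
  x <- as.matrix(x)
  stopifnot(!is.null(colnames(x)))
  d <- as_binary_labels(labels)
  ranges <- t(vapply(colnames(x), function(ft) {
    fit <- rroc.default(x[, ft], d, n_permutations = 0L)
    c(lo = fit$informative_range[1L], hi = fit$informative_range[2L],
      high = as.numeric(fit$part_opt == "high"))
  }, c(lo = 0, hi = 0, high = 0)))
  structure(list(
    features = colnames(x),
    range_lo = ranges[, "lo"],
    range_hi = ranges[, "hi"],
    part = ifelse(ranges[, "high"] == 1, "high", "low"),
    sentinel = sentinel
  ), class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat("Restriction map over", length(x$features), "features; sentinel =",
      x$sentinel, "\n")
  n_all <- sum(is.infinite(x$range_lo) & is.infinite(x$range_hi))
  cat(sprintf("  %d feature(s) keep all samples\n", n_all))
  invisible(x)
}

#' Sentinel-encode features outside their informative ranges
#'
#' Replaces every entry lying outside its feature's informative range with
#' the map's sentinel value; in-range entries are unchanged, so a keep-all
#' map is the identity and the transform is idempotent. The sentinel must
#' be strictly below every in-range value (so decision-tree splits either
#' fall inside the informative range or separate the sentinel from it);
#' with `sentinel = NULL` a per-column value of `min(in-range) - 1` is
#' chosen automatically with a warning.
#'
#' @param x numeric matrix/data frame, samples x features (columns named
#'   as in the map).
#' @param map a [fit_restriction_map()] result.
#' @return the transformed matrix.
#' @export
restrict_transform <- function(x, map) {
  stopifnot(inherits(map, "restriction_map"))
  x <- as.matrix(x)
  missing_ft <- setdiff(map$features, colnames(x))
  if (length(missing_ft)) {
    stop("features missing from data: ", paste(missing_ft, collapse = ", "))
  }
  out <- x
  for (ft in map$features) {
    inside <- in_informative_range(x[, ft],
                                   c(map$range_lo[[ft]], map$range_hi[[ft]]),
                                   map$part[[ft]])
    if (!any(!inside)) next
    sentinel <- map$sentinel
    if (is.null(sentinel)) {
      sentinel <- min(x[inside, ft]) - 1
      warning("auto-selected sentinel ", sentinel, " for feature ", ft)
    } else if (any(x[inside, ft] <= sentinel)) {
      stop("sentinel ", sentinel, " is not strictly below all in-range ",
           "values of feature ", ft,
           "; use sentinel = NULL for per-feature auto-selection")
    }
    out[!inside, ft] <- sentinel
  }
  out
}

#' Random-forest settings
#'
#' The fixed forest configuration used by [rroc_forest()]: 1000 trees,
#' maximum depth 20, minimum node size 1, `mtry = floor(sqrt(p))`,
#' per-tree subsampling of 63.2% without replacement, and a minimal split
#' gain of 1e-5 (exact split search, no histogram binning).
#'
#' @param n_trees,max_depth,min_node_size,sample_rate,min_split_improvement
#'   forest hyperparameters (see description for defaults).
#' @param mtry candidate features per split; default `floor(sqrt(p))` at
#'   fit time.
#' @param seed integer seed for reproducible forests.
#' @return a list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1000L, max_depth = 20L,
                          min_node_size = 1L, mtry = NULL,
                          sample_rate = 0.632,
                          min_split_improvement = 1e-5, seed = 1L) {
  stopifnot(n_trees >= 1L, max_depth >= 1L, min_node_size >= 1L,
            sample_rate > 0, sample_rate <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_node_size = as.integer(min_node_size), mtry = mtry,
                 sample_rate = sample_rate,
                 min_split_improvement = min_split_improvement,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Restriction-aware random forest
#'
#' Trains a probability random forest on (optionally sentinel-encoded)
#' biomarker features. When a [fit_restriction_map()] is supplied, the
#' training matrix is [restrict_transform()]ed first and `predict()`
#' applies the identical training-derived map to new data, so no
#' information flows from validation samples into the restriction.
#'
#' @param x numeric matrix/data frame, samples x features.
#' @param labels binary labels (both classes required).
#' @param map optional `restriction_map` fitted on the same training data.
#' @param config a [forest_config()].
#' @return an object of class `rroc_forest` wrapping the ranger model.
#' @export
rroc_forest <- function(x, labels, map = NULL, config = forest_config()) {
  x <- as.matrix(x)
  stopifnot(!is.null(colnames(x)), inherits(config, "forest_config"))
  d <- as_binary_labels(labels)
  if (length(unique(d)) < 2L) stop("training labels must contain both classes")
  if (!is.null(map)) x <- restrict_transform(x, map)
  if (any(!is.finite(x))) stop("features must be finite after transformation")
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(x)))) else config$mtry
  df <- data.frame(.class = factor(d, levels = c(0, 1)), x,
                   check.names = FALSE)
  rf <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = config$n_trees, mtry = mtry,
    min.node.size = config$min_node_size, max.depth = config$max_depth,
    sample.fraction = config$sample_rate, replace = FALSE,
    probability = TRUE, seed = config$seed, num.threads = 1L
  )
  structure(list(forest = rf, map = map, features = colnames(x),
                 config = config), class = "rroc_forest")
}

#' @export
print.rroc_forest <- function(x, ...) {
  cat(sprintf("Restriction-aware random forest: %d trees, %d features%s\n",
              x$config$n_trees, length(x$features),
              if (is.null(x$map)) " (unrestricted)" else
                " (sentinel-encoded)"))
  invisible(x)
}

#' Predict from a restriction-aware forest
#'
#' @param object an [rroc_forest()].
#' @param newdata samples x features matrix/data frame containing the
#'   training features.
#' @param type `"class"` for 0/1 predictions (positive-class probability
#'   > 0.5) or `"prob"` for positive-class probabilities.
#' @param ... unused.
#' @export
predict.rroc_forest <- function(object, newdata,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$map)) newdata <- restrict_transform(newdata, object$map)
  pr <- stats::predict(object$forest,
                       data = as.data.frame(newdata[, object$features,
                                                    drop = FALSE],
                                            check.names = FALSE))
  p_pos <- pr$predictions[, "1"]
  if (type == "prob") p_pos else as.integer(p_pos > 0.5)
}
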