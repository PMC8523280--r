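#' Random equal-size cross-validation folds
#'
#' Randomly and equally divides sample indices into folds whose sizes differ
#' by at most one (e.g. 2729 samples in 10 folds give nine folds of 273 and
#' one of 272). Assignment is plain random — no stratification — and
#' deterministic given the seed.
#'
#' @param n Number of samples.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `folds` disjoint integer vectors covering `1:n`.
#' @export
kfold_indices <- function(n, folds = 10, seed = 1) {
  n <- as.integer(n); folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("n (", n, ") must be >= folds (", folds, ")")
  perm <- local_seed(seed, sample.int(n))
  sizes <- rep(n %/% folds, folds)
  r <- n %% folds
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  split(perm, rep(seq_len(folds), times = sizes))
}

#' A grid-search cell: one full classifier configuration
#'
#' Bundles the feature and classifier settings evaluated jointly by
#' cross-validated grid search: embedding dimension (study grid 50-500 by
#' 50), RAKEL's subset size k (2-6) and subset count (10), the base
#' classifier spec, the multilabel scheme and the feature scheme.
#'
#' @param dimension Feature dimensionality this config consumes.
#' @param k RAKEL subset size (ignored for `scheme = "br"`).
#' @param m_subsets RAKEL subset count.
#' @param base A [base_spec()].
#' @param scheme `"rakel"` or `"br"`.
#' @param feature_scheme `"embedding"` or `"one-hot"`.
#' @return Object of class `grid_config`.
#' @export
grid_config <- function(dimension, k = 6, m_subsets = 10,
                        base = base_spec(), scheme = c("rakel", "br"),
                        feature_scheme = c("embedding", "one-hot")) {
  scheme <- match.arg(scheme)
  feature_scheme <- match.arg(feature_scheme)
  stopifnot(inherits(base, "base_spec"), dimension >= 1, k >= 1,
            m_subsets >= 1)
  structure(list(dimension = as.integer(dimension), k = as.integer(k),
                 m_subsets = as.integer(m_subsets), base = base,
                 scheme = scheme, feature_scheme = feature_scheme),
            class = "grid_config")
}

#' @export
print.grid_config <- function(x, ...) {
  cat(sprintf("%s / %s / dim %d%s\n", x$scheme, x$base$algorithm, x$dimension,
              if (x$scheme == "rakel")
                sprintf(" / k=%d m=%d", x$k, x$m_subsets) else ""))
  invisible(x)
}

fit_config <- function(x, y, config, seed) {
  if (config$scheme == "rakel") {
    base <- config$base; base$seed <- seed
    rakel(x, y, k = config$k, m_subsets = config$m_subsets, base = base,
          seed = seed)
  } else {
    base <- config$base; base$seed <- seed
    br(x, y, base = base)
  }
}

#' Tenfold cross-validation of one configuration
#'
#' Each fold is held out once: the model is trained on the other folds and
#' predicts the held-out samples, so each sample is predicted exactly once.
#' The four measurements are then computed once over the pooled out-of-fold
#' predictions (a single sum over all n samples, not a per-fold average).
#'
#' @param x Feature matrix.
#' @param y Binary label matrix aligned with `x`.
#' @param config A [grid_config()].
#' @param seed Integer seed controlling the fold assignment and all
#'   per-fold model randomness.
#' @param folds Number of folds (default 10).
#' @return Object of class `cv_result`: list with `config`, `record` (a
#'   `metrics_record`), `seed`, `folds`, `n_empty` (pooled count of empty
#'   predicted label sets) and `predictions` (the pooled binary matrix,
#'   rows in original sample order).
#' @export
cross_validate <- function(x, y, config, seed = 1, folds = 10) {
  stopifnot(inherits(config, "grid_config"))
  x <- as.matrix(x)
  y <- check_binary_labels(y)
  if (nrow(x) != nrow(y)) stop("x and y have different row counts")
  n <- nrow(x)
  assign_seeds <- derive_seeds(seed, c("folds", paste0("fold", seq_len(folds))))
  idx <- kfold_indices(n, folds, seed = assign_seeds[["folds"]])
  pred <- matrix(NA_integer_, n, ncol(y))
  n_empty <- 0L
  for (f in seq_along(idx)) {
    test <- idx[[f]]
    fit <- fit_config(x[-test, , drop = FALSE], y[-test, , drop = FALSE],
                      config, seed = assign_seeds[[paste0("fold", f)]])
    p <- predict(fit, x[test, , drop = FALSE])
    n_empty <- n_empty + (attr(p, "n_empty") %||% 0L)
    pred[test, ] <- p
  }
  stopifnot(!anyNA(pred))  # every sample predicted exactly once
  dimnames(pred) <- list(rownames(x), colnames(y))
  structure(list(config = config,
                 record = multilabel_metrics(unclass(y), pred,
                                             m_labels = ncol(y)),
                 seed = seed, folds = as.integer(folds),
                 n_empty = n_empty, predictions = pred),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  print(x$config)
  print(x$record)
  invisible(x)
}

#' Repeated cross-validation
#'
#' Runs `repeats` independent cross-validations with fold-assignment seeds
#' `base_seed, base_seed + 1, ...` to gauge how much the measurements move
#' with the random sample division (the study repeats its selected
#' classifier's tenfold CV 20 times).
#'
#' @inheritParams cross_validate
#' @param repeats Number of independent CV runs.
#' @param base_seed First seed.
#' @return Object of class `repeat_cv`: list of `cv_result` plus a `ranges`
#'   attribute, a 2 x 4 matrix of per-metric min and max.
#' @export
repeat_cv <- function(x, y, config, repeats = 20, base_seed = 1, folds = 10) {
  stopifnot(repeats >= 1)
  results <- lapply(seq_len(repeats) - 1L, function(i)
    cross_validate(x, y, config, seed = base_seed + i, folds = folds))
  vals <- vapply(results, function(r)
    c(r$record$exact_match, r$record$accuracy, r$record$hamming_loss,
      r$record$integrated_score), numeric(4))
  rownames(vals) <- c("exact_match", "accuracy", "hamming_loss",
                      "integrated_score")
  ranges <- rbind(min = apply(vals, 1, min), max = apply(vals, 1, max))
  structure(results, ranges = ranges, class = "repeat_cv")
}

#' @export
print.repeat_cv <- function(x, ...) {
  cat("Repeated cross-validation:", length(x), "runs\n")
  print(round(attr(x, "ranges"), 4))
  invisible(x)
}

#' Cross-validated grid search
#'
#' Evaluates every configuration by cross-validation and selects the one
#' with the highest integrated score. Ties are broken towards the simplest
#' model: fewer trees, then smaller dimension, then smaller k.
#'
#' @param features_by_dimension Named list mapping dimension (as character,
#'   e.g. `"350"`) to the feature matrix of that dimensionality.
#' @param y Binary label matrix.
#' @param grid List of [grid_config()] objects; each config's `dimension`
#'   must be a name of `features_by_dimension`.
#' @param seed Seed passed to every [cross_validate()] call (same fold
#'   assignments across configs).
#' @param folds Number of folds.
#' @return List with `best` (a `cv_result`) and `results` (all of them, in
#'   grid order).
#' @export
grid_search <- function(features_by_dimension, y, grid, seed = 1, folds = 10) {
  if (length(grid) == 0L) stop("empty grid")
  dims <- vapply(grid, function(g) as.character(g$dimension), character(1))
  missing_dims <- setdiff(unique(dims), names(features_by_dimension))
  if (length(missing_dims))
    stop("no feature matrix for dimension(s): ",
         paste(missing_dims, collapse = ", "))
  results <- lapply(grid, function(g)
    cross_validate(features_by_dimension[[as.character(g$dimension)]], y, g,
                   seed = seed, folds = folds))
  score <- vapply(results, function(r) r$record$integrated_score, numeric(1))
  trees <- vapply(grid, function(g) g$base$trees, integer(1))
  dimen <- vapply(grid, function(g) g$dimension, integer(1))
  kk <- vapply(grid, function(g) g$k, integer(1))
  best <- order(-score, trees, dimen, kk)[1]
  list(best = results[[best]], results = results)
}

#' Result table in the style of the published comparisons
#'
#' @param results List of `cv_result` objects (e.g. `grid_search()$results`).
#' @param path Optional TSV output path.
#' @return Data frame with scheme, base classifier, configuration and the
#'   four rounded measurements.
#' @export
results_table <- function(results, path = NULL) {
  df <- do.call(rbind, lapply(results, function(r) {
    g <- r$config
    data.frame(scheme = g$scheme, base = g$base$algorithm,
               dimension = g$dimension,
               k = if (g$scheme == "rakel") g$k else NA_integer_,
               m_subsets = if (g$scheme == "rakel") g$m_subsets else NA_integer_,
               trees = if (g$base$algorithm == "random_forest")
                 g$base$trees else NA_integer_,
               t(format_metrics(r$record)))
  }))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
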