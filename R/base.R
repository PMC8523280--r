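#' Base single-label classifier specification
#'
#' The label-powerset and binary-relevance ensembles are agnostic to the
#' single-label learner: anything satisfying fit(features, categorical
#' response) / predict(features) -> categorical works. Built-in algorithms:
#'
#' * `"random_forest"` — [randomForest::randomForest()]; tuned by `trees`
#'   (study grid 100-500 in steps of 100).
#' * `"svm_polynomial"` — [e1071::svm()] with polynomial kernel; tuned by
#'   `cost` (study grid 1-4) and `exponent` (1-4).
#' * `"svm_rbf"` — [e1071::svm()] with RBF kernel; tuned by `cost` and
#'   `gamma` (study grid 0.01-0.05).
#' * `"memorize"` — exact-recall learner used for algorithm verification:
#'   a query identical to a training row gets that row's class, anything
#'   else the majority class.
#' * `"majority"` — constant majority-class predictor (an uninformative
#'   reference).
#'
#' @param algorithm One of the algorithms above.
#' @param trees Number of trees (random forest).
#' @param cost Regularisation parameter C (SVM).
#' @param exponent Polynomial kernel degree.
#' @param gamma RBF kernel width.
#' @param seed Integer seed for stochastic learners.
#' @return Object of class `base_spec`.
#' @export
base_spec <- function(algorithm = c("random_forest", "svm_polynomial",
                                    "svm_rbf", "memorize", "majority"),
                      trees = 500, cost = 1, exponent = 1, gamma = 0.01,
                      seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(trees >= 1, cost > 0, exponent >= 1, gamma > 0)
  structure(list(algorithm = algorithm, trees = as.integer(trees),
                 cost = cost, exponent = as.integer(exponent), gamma = gamma,
                 seed = as.integer(seed)),
            class = "base_spec")
}

#' @export
print.base_spec <- function(x, ...) {
  extra <- switch(x$algorithm,
    random_forest = paste0("trees=", x$trees),
    svm_polynomial = paste0("C=", x$cost, ", exponent=", x$exponent),
    svm_rbf = paste0("C=", x$cost, ", gamma=", x$gamma),
    "")
  cat("Base classifier:", x$algorithm,
      if (nzchar(extra)) paste0("(", extra, ")") else "", "\n")
  invisible(x)
}

# Fit one single-label model. `y` is a factor; a single observed class yields
# a constant predictor (reported via message), never an error: a RAKEL label
# subset can legitimately collapse to one powerset class.
fit_base <- function(spec, x, y, seed = spec$seed) {
  stopifnot(inherits(spec, "base_spec"), is.matrix(x))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    message("single training class '", levels(y), "': constant predictor")
    return(structure(list(kind = "constant", level = levels(y)),
                     class = "mptype_base_fit"))
  }
  fit <- switch(spec$algorithm,
    random_forest = local_seed(seed,
      randomForest::randomForest(x, y, ntree = spec$trees)),
    svm_polynomial = e1071::svm(x, y, kernel = "polynomial",
                                cost = spec$cost, degree = spec$exponent,
                                scale = FALSE),
    svm_rbf = e1071::svm(x, y, kernel = "radial", cost = spec$cost,
                         gamma = spec$gamma, scale = FALSE),
    memorize = list(x = x, y = y,
                    majority = names(which.max(table(y)))),
    majority = list(level = names(which.max(table(y)))))
  structure(list(kind = spec$algorithm, fit = fit, levels = levels(y),
                 p = ncol(x)),
            class = "mptype_base_fit")
}

# Predict classes (character vector) for new rows.
predict_base <- function(model, x) {
  stopifnot(inherits(model, "mptype_base_fit"), is.matrix(x))
  if (model$kind == "constant")
    return(rep(model$level, nrow(x)))
  if (ncol(x) != model$p)
    stop("feature dimension mismatch: model expects ", model$p,
         " columns, got ", ncol(x))
  switch(model$kind,
    random_forest = as.character(predict(model$fit, x)),
    svm_polynomial = ,
    svm_rbf = as.character(predict(model$fit, x)),
    memorize = {
      tr <- model$fit
      vapply(seq_len(nrow(x)), function(i) {
        hit <- which(colSums(abs(t(tr$x) - x[i, ])) == 0)
        if (length(hit)) as.character(tr$y[hit[1]]) else tr$majority
      }, character(1))
    },
    majority = rep(model$fit$level, nrow(x)),
    stop("unknown base model kind: ", model$kind))
}
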