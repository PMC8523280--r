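#' Fit a Binary Relevance multilabel ensemble
#'
#' Binary Relevance trains one independent binary classifier per label on
#' that label's indicator column, ignoring label correlations. It is the
#' standard problem-transformation baseline against which RAKEL is compared.
#' A label whose training column is constant yields a constant predictor
#' (reported via message), not an error.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Binary label matrix (samples x labels).
#' @param base A [base_spec()]; per-label models use seeds
#'   `base$seed + label index`.
#' @return Object of class `br`: list with `models`, `l`, `label_names`,
#'   `base`, `p`, `call`.
#' @seealso [predict.br()], [rakel()]
#' @export
br <- function(x, y, base = base_spec()) {
  cl <- match.call()
  x <- as.matrix(x)
  y <- check_binary_labels(y)
  if (nrow(x) != nrow(y)) stop("x and y have different row counts")
  l <- ncol(y)
  label_names <- colnames(y) %||% paste0("L", seq_len(l))
  models <- lapply(seq_len(l), function(j)
    fit_base(base, x, factor(y[, j], levels = c(0L, 1L)),
             seed = base$seed + j))
  structure(list(models = models, l = l, label_names = label_names,
                 base = base, p = ncol(x), call = cl),
            class = "br")
}

#' Predict from a Binary Relevance ensemble
#'
#' @param object A fitted [br()] ensemble.
#' @param x Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Binary matrix (samples x labels); rows may be all-zero (the count
#'   is attached as attribute `n_empty`).
#' @export
predict.br <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$p)
    stop("feature dimension mismatch: model expects ", object$p,
         " columns, got ", ncol(x))
  resp <- vapply(object$models, function(m)
    as.integer(predict_base(m, x) == "1"), integer(nrow(x)))
  resp <- matrix(resp, nrow = nrow(x),
                 dimnames = list(rownames(x), object$label_names))
  attr(resp, "n_empty") <- sum(rowSums(resp) == 0)
  resp
}

#' @export
print.br <- function(x, ...) {
  cat("Binary Relevance multilabel ensemble\n")
  cat("  labels:", x$l, "| base:", x$base$algorithm, "\n")
  invisible(x)
}
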