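# Accept either a binary matrix or a list of label-index sets; return the
# list-of-sets view.
as_label_sets <- function(x) {
  if (is.matrix(x) || inherits(x, "label_matrix")) return(label_sets(x))
  if (is.list(x)) return(lapply(x, function(s) sort(unique(as.integer(s)))))
  stop("labels must be a binary matrix or a list of label-index sets")
}

check_paired <- function(truth, pred) {
  truth <- as_label_sets(truth); pred <- as_label_sets(pred)
  if (length(truth) != length(pred))
    stop("true and predicted label lists have different lengths")
  if (length(truth) == 0L) stop("no samples to evaluate")
  list(truth = truth, pred = pred)
}

#' Exact match
#'
#' Fraction of samples whose predicted label set is identical to the true
#' set: `(1/n) * sum_i I(L_i == L_i')`.
#'
#' @param truth,pred Binary label matrices (samples x labels) or lists of
#'   label-index sets, equal length.
#' @return A number in \[0, 1\].
#' @export
exact_match <- function(truth, pred) {
  z <- check_paired(truth, pred)
  mean(mapply(function(a, b) setequal(a, b), z$truth, z$pred))
}

#' Jaccard accuracy
#'
#' Mean over samples of `|L_i intersect L_i'| / |L_i union L_i'|`. A sample
#' where both sets are empty contributes 1 (a perfectly predicted empty set
#' is not penalised; the 0/0 case never arises in the membrane-protein data,
#' where every protein has at least one type).
#'
#' @inheritParams exact_match
#' @return A number in \[0, 1\].
#' @export
accuracy_jaccard <- function(truth, pred) {
  z <- check_paired(truth, pred)
  mean(mapply(function(a, b) {
    u <- union(a, b)
    if (length(u) == 0L) 1 else length(intersect(a, b)) / length(u)
  }, z$truth, z$pred))
}

#' Hamming loss
#'
#' Mean over samples of the symmetric-difference size between true and
#' predicted label sets, divided by the number of labels:
#' `(1/n) * sum_i |L_i delta L_i'| / m`, with m = 6 for the six membrane
#' protein types.
#'
#' @inheritParams exact_match
#' @param m_labels Size of the label universe; defaults to the column count
#'   when matrices are supplied.
#' @return A number in \[0, 1\].
#' @export
hamming_loss <- function(truth, pred, m_labels = NULL) {
  if (is.null(m_labels)) {
    if (is.matrix(truth)) m_labels <- ncol(truth)
    else if (is.matrix(pred)) m_labels <- ncol(pred)
    else stop("m_labels is required when label sets are given as lists")
  }
  z <- check_paired(truth, pred)
  mx <- suppressWarnings(max(c(unlist(z$truth), unlist(z$pred), 0L)))
  if (mx > m_labels) stop("label index ", mx, " exceeds m_labels = ", m_labels)
  mean(mapply(function(a, b)
    (length(setdiff(a, b)) + length(setdiff(b, a))) / m_labels,
    z$truth, z$pred))
}

#' Integrated score
#'
#' The single model-selection criterion combining the three multilabel
#' measurements: `exact_match * accuracy * (1 - hamming_loss)`. Reported to
#' four decimal places in result tables.
#'
#' @param exact_match,accuracy,hamming_loss Numbers in \[0, 1\].
#' @return A number in \[0, 1\].
#' @export
integrated_score <- function(exact_match, accuracy, hamming_loss) {
  vals <- c(exact_match, accuracy, hamming_loss)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("all inputs must lie in [0, 1]")
  exact_match * accuracy * (1 - hamming_loss)
}

#' Full multilabel evaluation record
#'
#' Computes exact match, Jaccard accuracy, hamming loss and the integrated
#' score for one set of predictions.
#'
#' @inheritParams hamming_loss
#' @return Object of class `metrics_record`: list with `exact_match`,
#'   `accuracy`, `hamming_loss`, `integrated_score`, `n`, `m_labels`.
#' @export
multilabel_metrics <- function(truth, pred, m_labels = NULL) {
  if (is.null(m_labels) && is.matrix(truth)) m_labels <- ncol(truth)
  em <- exact_match(truth, pred)
  acc <- accuracy_jaccard(truth, pred)
  hl <- hamming_loss(truth, pred, m_labels)
  structure(list(exact_match = em, accuracy = acc, hamming_loss = hl,
                 integrated_score = integrated_score(em, acc, hl),
                 n = length(as_label_sets(truth)),
                 m_labels = as.integer(m_labels)),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(paste0("Multilabel evaluation over %d samples (%d labels)\n",
                     "  exact match:      %.3f\n",
                     "  accuracy:         %.3f\n",
                     "  hamming loss:     %.3f\n",
                     "  integrated score: %.4f\n"),
              x$n, x$m_labels, x$exact_match, x$accuracy, x$hamming_loss,
              x$integrated_score))
  invisible(x)
}

#' Round a metrics record the way result tables print it
#'
#' Measurements to 3 decimals, integrated score to 4.
#'
#' @param record A `metrics_record`.
#' @return Named numeric vector of the four rounded values.
#' @export
format_metrics <- function(record) {
  stopifnot(inherits(record, "metrics_record"))
  c(exact_match = round(record$exact_match, 3),
    accuracy = round(record$accuracy, 3),
    hamming_loss = round(record$hamming_loss, 3),
    integrated_score = round(record$integrated_score, 4))
}

#' Serialize a metrics record to JSON
#'
#' @param record A `metrics_record`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
metrics_to_json <- function(record, path = NULL) {
  stopifnot(inherits(record, "metrics_record"))
  js <- jsonlite::toJSON(unclass(record), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
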