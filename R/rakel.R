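# -- label-powerset plumbing ------------------------------------------------

# A powerset class is a (possibly empty) subset of a label subset, treated as
# one categorical class. Encoded canonically as "{i,j,...}" over sorted
# 1-based label indices, "{}" for the empty class.
encode_powerset <- function(members) {
  paste0("{", paste(sort(as.integer(members)), collapse = ","), "}")
}

decode_powerset <- function(code) {
  inner <- sub("^\\{(.*)\\}$", "\\1", code)
  if (!nzchar(inner)) return(integer(0))
  as.integer(strsplit(inner, ",", fixed = TRUE)[[1]])
}

#' Restrict a label set to a label subset
#'
#' The label-powerset transformation step: of a sample's labels, those inside
#' the subset are picked up and the rest discarded, and the remainder is
#' treated as a single new categorical class. E.g. labels \{1, 2, 4\}
#' restricted to the subset \{1, 2, 3\} give the powerset class \{1, 2\}.
#'
#' @param labels Integer vector of 1-based label indices held by a sample.
#' @param subset Integer vector of 1-based label indices (a label subset).
#' @return Sorted integer vector `intersect(labels, subset)`, with the
#'   canonical class code as attribute `code`.
#' @export
restrict_labels <- function(labels, subset) {
  members <- sort(intersect(as.integer(labels), as.integer(subset)))
  structure(members, code = encode_powerset(members))
}

#' Sample random label subsets
#'
#' Draws `m_subsets` subsets of `k` of the `l` labels. While `choose(l, k)`
#' is at least `m_subsets`, subsets are sampled without replacement (all
#' distinct); otherwise sampling falls back to with-replacement draws (with a
#' message) — necessary because settings such as k = l with several subsets
#' force duplicates.
#'
#' @param l Number of labels.
#' @param k Subset size, `1 <= k <= l`.
#' @param m_subsets Number of subsets to draw.
#' @param seed Integer seed.
#' @return List of `m_subsets` strictly increasing integer vectors.
#' @export
sample_label_subsets <- function(l, k, m_subsets, seed = 1) {
  l <- as.integer(l); k <- as.integer(k); m_subsets <- as.integer(m_subsets)
  if (k < 1L || k > l) stop("k must satisfy 1 <= k <= l")
  if (m_subsets < 1L) stop("m_subsets must be >= 1")
  total <- choose(l, k)
  if (total >= m_subsets && total <= 1e5) {
    all_sub <- utils::combn(l, k)
    pick <- local_seed(seed, sample.int(ncol(all_sub), m_subsets))
    lapply(pick, function(j) all_sub[, j])
  } else if (total >= m_subsets) {
    # too many subsets to enumerate: rejection-sample distinct ones
    local_seed(seed, {
      seen <- character(0)
      out <- vector("list", m_subsets)
      i <- 0L
      while (i < m_subsets) {
        s <- sort(sample.int(l, k))
        key <- paste(s, collapse = ",")
        if (!key %in% seen) {
          i <- i + 1L
          out[[i]] <- s
          seen <- c(seen, key)
        }
      }
      out
    })
  } else {
    message("choose(", l, ",", k, ") = ", total, " < ", m_subsets,
            " subsets requested: sampling with replacement")
    local_seed(seed,
      lapply(seq_len(m_subsets), function(j) sort(sample.int(l, k))))
  }
}

# rows of a binary matrix as a list of 1-based label-index sets
label_sets <- function(y) {
  y <- unclass(as.matrix(y))
  lapply(seq_len(nrow(y)), function(i) which(y[i, ] == 1))
}

check_binary_labels <- function(y) {
  y <- as.matrix(unclass(y))
  storage.mode(y) <- "integer"
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) stop("labels must be binary")
  y
}

# -- RAKEL ------------------------------------------------------------------

#' Fit a RAKEL (random k-labelsets) multilabel ensemble
#'
#' RAKEL turns an l-label multilabel problem into `m_subsets` single-label
#' problems: each of `m_subsets` random label subsets of size `k` induces a
#' label-powerset classifier whose classes are the subsets of that label
#' subset observed in training (each training sample gets exactly one such
#' class — its labels restricted to the subset). At prediction time every
#' label is voted on by the classifiers whose subset contains it, and is
#' assigned when the proportion of those classifiers predicting it strictly
#' exceeds `threshold`.
#'
#' The default configuration (k = 6, 10 subsets, a 500-tree random forest
#' base) is the one selected by integrated-score grid search on the human
#' membrane-protein problem. Duplicate subsets (inevitable when k = l) are
#' decorrelated through per-model base seeds `base$seed + model index`.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Binary label matrix (samples x labels); every row must have at
#'   least one positive label.
#' @param k Label subset size, `1 <= k <= ncol(y)`.
#' @param m_subsets Number of label subsets / base models.
#' @param base A [base_spec()].
#' @param threshold Vote threshold tau in (0, 1); a label needs a vote
#'   proportion strictly greater than tau (an exact tie at tau is negative).
#' @param seed Integer seed for subset sampling.
#' @return Object of class `rakel`: list with `subsets`, `models`, `l`,
#'   `label_names`, `k`, `m_subsets`, `threshold`, `base`, `seed`, `p`
#'   (feature dimension) and `call`.
#' @seealso [predict.rakel()], [br()]
#' @export
rakel <- function(x, y, k = ncol(y), m_subsets = 10, base = base_spec(),
                  threshold = 0.5, seed = 1) {
  cl <- match.call()
  x <- as.matrix(x)
  y <- check_binary_labels(y)
  if (nrow(x) != nrow(y)) stop("x and y have different row counts")
  if (any(rowSums(y) == 0L)) stop("every training sample needs >= 1 label")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  l <- ncol(y)
  label_names <- colnames(y) %||% paste0("L", seq_len(l))
  subsets <- sample_label_subsets(l, k, m_subsets, seed)
  sets <- label_sets(y)
  models <- vector("list", length(subsets))
  for (j in seq_along(subsets)) {
    classes <- vapply(sets, function(s) encode_powerset(intersect(s, subsets[[j]])),
                      character(1))
    models[[j]] <- fit_base(base, x, factor(classes), seed = base$seed + j)
  }
  structure(list(subsets = subsets, models = models, l = l,
                 label_names = label_names, k = as.integer(k),
                 m_subsets = as.integer(m_subsets), threshold = threshold,
                 base = base, seed = as.integer(seed), p = ncol(x),
                 call = cl),
            class = "rakel")
}

#' Predict from a RAKEL ensemble
#'
#' For each label j, the vote proportion is the fraction of ensemble members
#' whose subset contains j that predict a powerset class including j; the
#' label is assigned when that proportion strictly exceeds the ensemble's
#' threshold. Labels covered by no subset get proportion 0.
#'
#' @param object A fitted [rakel()] ensemble.
#' @param x Feature matrix with the training dimensionality.
#' @param type `"response"` for the binary prediction matrix (with the count
#'   of empty predicted label sets as attribute `n_empty`), `"votes"` for the
#'   matrix of vote proportions.
#' @param ... Unused.
#' @return Numeric matrix (samples x labels), per `type`.
#' @export
predict.rakel <- function(object, x, type = c("response", "votes"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != object$p)
    stop("feature dimension mismatch: model expects ", object$p,
         " columns, got ", ncol(x))
  n <- nrow(x); l <- object$l
  num <- matrix(0, n, l)
  den <- tabulate(unlist(object$subsets), nbins = l)
  for (j in seq_along(object$models)) {
    preds <- predict_base(object$models[[j]], x)
    members <- lapply(preds, decode_powerset)
    for (lab in object$subsets[[j]]) {
      num[, lab] <- num[, lab] +
        vapply(members, function(m) lab %in% m, logical(1))
    }
  }
  votes <- sweep(num, 2, pmax(den, 1L), "/")
  votes[, den == 0L] <- 0
  dimnames(votes) <- list(rownames(x), object$label_names)
  if (type == "votes") return(votes)
  resp <- (votes > object$threshold) + 0
  attr(resp, "n_empty") <- sum(rowSums(resp) == 0)
  resp
}

#' @export
print.rakel <- function(x, ...) {
  cat("RAKEL multilabel ensemble\n")
  cat("  labels:", x$l, "| subset size k:", x$k,
      "| subsets m:", x$m_subsets, "| threshold:", x$threshold, "\n")
  cat("  base:", x$base$algorithm, "\n")
  invisible(x)
}

#' @export
summary.rakel <- function(object, ...) {
  cat("RAKEL multilabel ensemble (", object$m_subsets, " models over ",
      object$l, " labels)\n", sep = "")
  for (j in seq_along(object$subsets)) {
    mod <- object$models[[j]]
    ncl <- if (mod$kind == "constant") 1L else length(mod$levels)
    cat(sprintf("  model %2d: subset {%s}, %d powerset class(es)%s\n", j,
                paste(object$label_names[object$subsets[[j]]], collapse = ", "),
                ncl, if (mod$kind == "constant") " [constant]" else ""))
  }
  cov <- tabulate(unlist(object$subsets), nbins = object$l)
  if (any(cov == 0L))
    cat("  WARNING: label(s) never covered:",
        paste(object$label_names[cov == 0L], collapse = ", "), "\n")
  invisible(object)
}
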