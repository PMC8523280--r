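#' Specification for a synthetic membrane-protein annotation dataset
#'
#' The generator emulates the statistical shape of the human membrane
#' protein study without any database download: `l` protein types (default
#' 6), a heavily skewed label multiplicity (by default the real study's
#' proportions — 2652 single-type, 73 two-type and 4 three-type proteins out
#' of 2729, i.e. about 97% single-label), one pool of type-specific domain
#' terms per type, plus a shared pool of uninformative background terms. The
#' `signal` fraction of each protein's terms is drawn from its own types'
#' pools, the rest from the background, so `signal = 1` with disjoint pools
#' makes the types perfectly recoverable and `signal = 0` removes all
#' information.
#'
#' @param n_proteins Number of proteins (the real study has 2729).
#' @param l Number of types.
#' @param pool_size Type-specific terms per type pool.
#' @param background_size Shared uninformative terms.
#' @param multiplicity_probs Probabilities of a protein carrying 1, 2, ...
#'   types (sums to 1; default the real study's multiplicity distribution,
#'   capping multiplicity at 3 as observed there).
#' @param terms_per_protein Integer range `c(min, max)` of terms per protein
#'   (uniform draw; min >= 1).
#' @param signal Fraction of a protein's terms drawn from its type pools.
#' @param label_names Type names (default [membrane_types()] when `l = 6`).
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 2729, l = 6, pool_size = 8,
                           background_size = 20,
                           multiplicity_probs = c(2652, 73, 4) / 2729,
                           terms_per_protein = c(3, 8), signal = 0.8,
                           label_names = NULL, seed = 1) {
  stopifnot(n_proteins >= 1, l >= 2, pool_size >= 1, background_size >= 0,
            length(terms_per_protein) == 2, signal >= 0, signal <= 1)
  if (terms_per_protein[1] < 1) stop("terms_per_protein lower bound must be >= 1")
  if (terms_per_protein[1] > terms_per_protein[2])
    stop("terms_per_protein must be an increasing range")
  if (abs(sum(multiplicity_probs) - 1) > 1e-8)
    stop("multiplicity_probs must sum to 1")
  if (length(multiplicity_probs) > l)
    stop("multiplicity cannot exceed the number of types")
  if (signal < 1 && background_size < 1)
    stop("background_size must be >= 1 when signal < 1")
  if (is.null(label_names))
    label_names <- if (l == 6) membrane_types() else paste0("type", seq_len(l))
  stopifnot(length(label_names) == l)
  structure(list(n_proteins = as.integer(n_proteins), l = as.integer(l),
                 pool_size = as.integer(pool_size),
                 background_size = as.integer(background_size),
                 multiplicity_probs = multiplicity_probs,
                 terms_per_protein = as.integer(terms_per_protein),
                 signal = signal, label_names = label_names,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic annotation + label dataset
#'
#' Draws, per protein: its label multiplicity from the spec's distribution,
#' its types uniformly without replacement, a term count uniform in the
#' spec's range, and its terms — a `signal` fraction (rounded) sampled
#' without replacement from the union of its types' pools, the remainder
#' from the background pool. Every protein ends up with at least one term.
#' Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `annotations` (an [annotation_table()]) and `labels`
#'   (a [label_matrix()]).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pools <- lapply(seq_len(spec$l), function(t)
    sprintf("D%d.%02d", t, seq_len(spec$pool_size)))
  background <- if (spec$background_size > 0)
    sprintf("B.%03d", seq_len(spec$background_size)) else character(0)
  ids <- sprintf("SYN%05d", seq_len(spec$n_proteins))

  local_seed(spec$seed, {
    mult <- sample.int(length(spec$multiplicity_probs), spec$n_proteins,
                       replace = TRUE, prob = spec$multiplicity_probs)
    ind <- matrix(0L, spec$n_proteins, spec$l,
                  dimnames = list(ids, spec$label_names))
    terms <- vector("list", spec$n_proteins)
    for (i in seq_len(spec$n_proteins)) {
      types <- sample.int(spec$l, mult[i])
      ind[i, types] <- 1L
      n_terms <- sample(spec$terms_per_protein[1]:spec$terms_per_protein[2], 1)
      own <- unlist(pools[types], use.names = FALSE)
      n_sig <- min(round(spec$signal * n_terms), length(own))
      n_bg <- min(n_terms - n_sig, length(background))
      if (n_sig + n_bg == 0L) {  # degenerate settings still need >= 1 term
        if (spec$signal > 0) n_sig <- 1L else n_bg <- 1L
      }
      tk <- c(if (n_sig > 0) sample(own, n_sig),
              if (n_bg > 0) sample(background, n_bg))
      terms[[i]] <- sample(tk)  # shuffle so pool terms are not grouped
    }
    list(annotations = annotation_table(stats::setNames(terms, ids)),
         labels = label_matrix(ind))
  })
}

#' Frozen 12-protein toy fixture
#'
#' A fixed dataset used by unit tests and examples: 12 proteins over 3
#' labels and 9 domain terms, with ten single-label proteins, one two-label
#' and one three-label protein (multiplicity counts \{1: 10, 2: 1, 3: 1\}).
#' Identical on every call.
#'
#' @return List with `annotations` and `labels` as in [generate_dataset()].
#' @export
generate_fixture_small <- function() {
  terms <- list(
    F01 = c("a1", "a2"), F02 = c("a1", "a3"), F03 = c("a2", "a3"),
    F04 = c("a3", "b1"), F05 = c("b1", "b2"), F06 = c("b2", "b3"),
    F07 = c("b1", "b3"), F08 = c("c1", "c2"), F09 = c("c2", "c3"),
    F10 = c("c1", "c3"),
    F11 = c("a1", "b1"),            # two-label protein
    F12 = c("a2", "b2", "c2"))      # three-label protein
  ind <- rbind(
    c(1, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 0, 0),
    c(0, 1, 0), c(0, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(0, 0, 1), c(0, 0, 1),
    c(1, 1, 0),
    c(1, 1, 1))
  dimnames(ind) <- list(names(terms), c("alpha", "beta", "gamma"))
  list(annotations = annotation_table(terms), labels = label_matrix(ind))
}

#' Write a dataset as the standard annotation/label TSV pair
#'
#' @param dataset List with `annotations` and `labels`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- file.path(dir, "annotations.tsv")
  lab <- file.path(dir, "labels.tsv")
  write_annotations(dataset$annotations, ann)
  write_labels(dataset$labels, lab)
  invisible(c(annotations = ann, labels = lab))
}
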