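#' Build the domain-sentence corpus
#'
#' Each protein's domain term list becomes one "sentence" whose words are the
#' term tokens. Domain sets are unordered in the source databases, so the
#' default orders tokens lexicographically, making the corpus independent of
#' annotation-file row order; `"file-order"` keeps first-occurrence order.
#'
#' @param annotations An [annotation_table()].
#' @param ordering `"lexicographic"` (default) or `"file-order"`.
#' @return Named list of character vectors, one sentence per protein, in
#'   protein order.
#' @export
build_corpus <- function(annotations, ordering = c("lexicographic", "file-order")) {
  ordering <- match.arg(ordering)
  stopifnot(inherits(annotations, "annotation_table"))
  sentences <- annotations$terms
  if (ordering == "lexicographic")
    sentences <- lapply(sentences, function(s) sort(s, method = "radix"))
  sentences
}

#' Average-of-term-vectors protein features
#'
#' Represents each protein by the arithmetic mean of the embedding vectors of
#' its domain terms (e.g. a protein annotated with three IPR terms gets the
#' average of those three term vectors). Terms absent from the embedding
#' vocabulary are skipped; a protein with no in-vocabulary terms gets the
#' zero vector and a warning, rather than being dropped — exclusion of
#' unannotatable proteins is the job of [filter_annotated()].
#'
#' @param annotations An [annotation_table()].
#' @param embeddings An [embedding_table()].
#' @return Numeric matrix (proteins x dimension) with protein ids as
#'   rownames and attribute `scheme = "embedding-average"`.
#' @export
protein_vectors <- function(annotations, embeddings) {
  stopifnot(inherits(annotations, "annotation_table"),
            inherits(embeddings, "embedding_table"))
  V <- embeddings$vectors
  if (nrow(V) == 0L) stop("embedding table is empty")
  n <- length(annotations$protein_ids)
  out <- matrix(0, n, embeddings$dimension,
                dimnames = list(annotations$protein_ids, NULL))
  n_zero <- 0L
  for (i in seq_len(n)) {
    hit <- intersect(annotations$terms[[i]], rownames(V))
    if (length(hit) == 0L) {
      n_zero <- n_zero + 1L
    } else {
      out[i, ] <- colMeans(V[hit, , drop = FALSE])
    }
  }
  if (n_zero > 0L)
    warning(n_zero, " protein(s) had no in-vocabulary terms and were encoded ",
            "as zero vectors")
  attr(out, "scheme") <- "embedding-average"
  out
}

#' One-hot domain composition encoding
#'
#' The baseline encoding: a binary vector per protein with one component per
#' vocabulary term, set to 1 iff the term is annotated on the protein.
#' Out-of-vocabulary terms are ignored (their count is reported in a
#' message).
#'
#' @param annotations An [annotation_table()].
#' @param vocabulary Ordered character vector of domain terms defining the
#'   columns. Defaults to the distinct terms of `annotations` in
#'   lexicographic order.
#' @return Binary numeric matrix (proteins x terms) with dimnames and
#'   attribute `scheme = "one-hot"`.
#' @export
one_hot_encode <- function(annotations,
                           vocabulary = sort(unique(unlist(annotations$terms,
                                                           use.names = FALSE)))) {
  stopifnot(inherits(annotations, "annotation_table"))
  if (length(vocabulary) == 0L) stop("vocabulary must be non-empty")
  if (anyDuplicated(vocabulary)) stop("vocabulary has duplicate terms")
  n <- length(annotations$protein_ids)
  out <- matrix(0, n, length(vocabulary),
                dimnames = list(annotations$protein_ids, vocabulary))
  n_oov <- 0L
  zero_rows <- character(0)
  for (i in seq_len(n)) {
    tk <- annotations$terms[[i]]
    hit <- tk %in% vocabulary
    n_oov <- n_oov + sum(!hit)
    if (!any(hit)) zero_rows <- c(zero_rows, annotations$protein_ids[i])
    out[i, tk[hit]] <- 1
  }
  if (n_oov > 0L)
    message(n_oov, " out-of-vocabulary term annotation(s) ignored")
  if (length(zero_rows))
    warning(length(zero_rows), " protein(s) had no vocabulary terms ",
            "(all-zero rows)")
  attr(out, "scheme") <- "one-hot"
  out
}

#' Write / read a protein feature matrix as TSV
#'
#' Serialized with the protein identifier as first column and 17 significant
#' digits so that write/read round-trips are bit-exact for doubles.
#'
#' @param features Numeric matrix with protein ids as rownames.
#' @param path File path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the matrix (with `scheme` attribute restored from the header
#'   comment when present).
#' @export
write_features <- function(features, path) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  con <- file(path, "w")
  on.exit(close(con))
  scheme <- attr(features, "scheme")
  if (!is.null(scheme)) writeLines(paste0("#scheme=", scheme), con)
  writeLines(paste0("protein_id\t",
                    paste0("f", seq_len(ncol(features)), collapse = "\t")), con)
  body <- vapply(seq_len(nrow(features)), function(i)
    paste(rownames(features)[i],
          paste(sprintf("%.17g", features[i, ]), collapse = "\t"), sep = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  scheme <- if (grepl("^#scheme=", first)) sub("^#scheme=", "", first) else NULL
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = NA)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- NULL
  if (!is.null(scheme)) attr(m, "scheme") <- scheme
  m
}
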