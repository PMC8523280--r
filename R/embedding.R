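#' Construct an embedding table
#'
#' @param vectors Numeric matrix (terms x dimension) with term tokens as
#'   rownames.
#' @param hyperparameters Named list recording how the vectors were trained.
#' @return Object of class `embedding_table` with elements `dimension`,
#'   `vectors`, `hyperparameters`.
#' @export
embedding_table <- function(vectors, hyperparameters = list()) {
  stopifnot(is.matrix(vectors), is.numeric(vectors), !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors))) stop("duplicate terms in embedding table")
  structure(list(dimension = ncol(vectors), vectors = vectors,
                 hyperparameters = hyperparameters),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  hp <- x$hyperparameters
  cat("Embedding table:", nrow(x$vectors), "terms x", x$dimension, "dims")
  if (length(hp))
    cat(" (", paste(names(hp), unlist(hp), sep = "=", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Train word-embedding vectors for domain terms
#'
#' Treats each protein's domain-term list as a sentence and learns a vector
#' per term with a word2vec-style neural embedding: CBOW (default) or
#' skip-gram, optimised by negative sampling with a dynamically shrunk
#' context window and a linearly decaying learning rate. Training is
#' single-threaded and driven by an internal generator, so results are
#' bit-reproducible given the same corpus, hyperparameters and seed.
#'
#' Defaults follow common word2vec practice (CBOW, window 5, 5 negative
#' samples, 5 epochs) with two deliberate exceptions suited to domain
#' sentences: `min_count = 1` because sentences are short and rare domains
#' are informative (dropping them would silently zero out proteins), and
#' frequent-word subsampling off (`sample = 0`) because in a vocabulary of a
#' few thousand terms every term exceeds the usual frequency threshold and
#' subsampling would discard most of an already short corpus.
#'
#' @param corpus Named list of character vectors as from [build_corpus()].
#' @param dimension Embedding dimensionality (the study grid spans 50 to 500
#'   in steps of 50; default 100).
#' @param window Maximum context window half-width; use `window = "max"` to
#'   cover whole sentences (domain sets are unordered, so truncating the
#'   window is arbitrary — the default keeps the conventional value 5).
#' @param min_count Minimum corpus frequency for a term to enter the
#'   vocabulary.
#' @param epochs Training passes over the corpus.
#' @param negative Negative samples per positive example.
#' @param architecture `"cbow"` or `"skip-gram"`.
#' @param alpha,min_alpha Initial and floor learning rates.
#' @param sample Frequent-word subsampling threshold (0 disables).
#' @param seed Integer seed for the internal generator.
#' @return An [embedding_table()]; `hyperparameters` records every setting.
#' @export
train_domain_embeddings <- function(corpus, dimension = 100, window = 5,
                                    min_count = 1, epochs = 5, negative = 5,
                                    architecture = c("cbow", "skip-gram"),
                                    alpha = 0.025, min_alpha = 1e-4,
                                    sample = 0, seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(dimension >= 1, length(corpus) >= 1, epochs >= 1, negative >= 0)
  corpus <- lapply(corpus, as.character)
  if (any(lengths(corpus) == 0L)) stop("corpus contains empty sentences")

  if (identical(window, "max")) window <- max(lengths(corpus))
  window <- as.integer(window)
  stopifnot(window >= 1)

  counts <- table(unlist(corpus, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L)
    stop("vocabulary is empty after min_count filtering; use min_count = 1")
  # frequency-descending, token-ascending: deterministic regardless of
  # sentence order in the input
  ord <- order(-as.integer(counts), names(counts), method = "radix")
  vocab <- names(counts)[ord]
  freq <- as.integer(counts)[ord]

  ids <- lapply(corpus, function(s) {
    i <- match(s, vocab)
    as.integer(i[!is.na(i)] - 1L)
  })
  ids <- ids[lengths(ids) > 0L]
  if (length(ids) == 0L)
    stop("no sentence retains any vocabulary term; use min_count = 1")

  vec <- w2v_train_cpp(ids, length(vocab), freq, as.integer(dimension),
                       window, as.integer(negative), as.integer(epochs),
                       alpha, min_alpha, architecture == "cbow", sample,
                       as.integer(seed))
  rownames(vec) <- vocab
  embedding_table(vec, hyperparameters = list(
    architecture = architecture, dimension = as.integer(dimension),
    window = window, min_count = min_count, epochs = epochs,
    negative = negative, alpha = alpha, min_alpha = min_alpha,
    sample = sample, seed = as.integer(seed)))
}

#' Write / read embeddings in word2vec text format
#'
#' The standard text layout: a header line `|V| d`, then one line per term
#' with the token followed by `d` space-separated coordinates (written at 17
#' significant digits so round-trips are value-exact).
#'
#' @param embeddings An [embedding_table()].
#' @param path File path.
#' @return `write_embeddings()` returns `path` invisibly; `read_embeddings()`
#'   returns an [embedding_table()] (hyperparameters are not stored in this
#'   format and come back empty).
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(inherits(embeddings, "embedding_table"))
  V <- embeddings$vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(V), ncol(V)), con)
  writeLines(vapply(seq_len(nrow(V)), function(i)
    paste(rownames(V)[i], paste(sprintf("%.17g", V[i, ]), collapse = " ")),
    character(1)), con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("not a word2vec text file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || any(is.na(hdr)))
    stop("malformed word2vec header in ", path)
  nv <- hdr[1]; d <- hdr[2]
  if (length(lines) < nv + 1L) stop("truncated word2vec file: ", path)
  toks <- character(nv)
  vec <- matrix(NA_real_, nv, d)
  for (i in seq_len(nv)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != d + 1L)
      stop("malformed vector line ", i + 1L, " in ", path)
    toks[i] <- parts[1]
    vec[i, ] <- as.numeric(parts[-1])
  }
  rownames(vec) <- toks
  embedding_table(vec)
}
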