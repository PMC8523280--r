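# Shared fixtures and independent oracles for the test suite.

# write lines to a temp file, return its path
tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a RAKEL object whose models are constant predictors emitting fixed
# powerset-class codes; used for hand-checkable vote arithmetic
fake_rakel <- function(subsets, codes, l, p = 2, threshold = 0.5) {
  stopifnot(length(subsets) == length(codes))
  models <- lapply(codes, function(cd)
    structure(list(kind = "constant", level = cd), class = "mptype_base_fit"))
  structure(list(subsets = lapply(subsets, as.integer), models = models,
                 l = l, label_names = paste0("L", seq_len(l)),
                 k = length(subsets[[1]]), m_subsets = length(subsets),
                 threshold = threshold, base = base_spec("majority"),
                 seed = 1L, p = p, call = quote(fake_rakel())),
            class = "rakel")
}

# independent parser for powerset-class codes like "{1,3}"
oracle_parse_class <- function(code) {
  body <- gsub("[{}]", "", code)
  if (!nzchar(body)) integer(0) else as.integer(strsplit(body, ",")[[1]])
}

# independent per-label vote counting: given the subsets and each model's
# predicted class codes for n samples, tally votes label by label
oracle_votes <- function(subsets, pred_codes_by_model, l, n) {
  votes <- matrix(0, n, l)
  for (j in seq_len(l)) {
    involved <- which(vapply(subsets, function(s) j %in% s, logical(1)))
    if (length(involved) == 0L) next
    for (i in seq_len(n)) {
      yes <- sum(vapply(involved, function(mdl)
        j %in% oracle_parse_class(pred_codes_by_model[[mdl]][i]), logical(1)))
      votes[i, j] <- yes / length(involved)
    }
  }
  votes
}

# random small multilabel dataset with distinct feature rows (so the
# memorizing base recalls every training sample exactly)
random_multilabel <- function(n, l, seed) {
  withr::with_seed(seed, {
    x <- matrix(round(stats::runif(n * 3), 6), n, 3)
    x[, 1] <- seq_len(n)  # force distinct rows
    y <- matrix(0L, n, l)
    for (i in seq_len(n)) y[i, sample.int(l, sample.int(min(3, l), 1))] <- 1L
    list(x = x, y = y)
  })
}

# mean cosine similarity between rows of two vector sets
mean_cosine <- function(V, idx_a, idx_b) {
  Vn <- V / sqrt(rowSums(V^2))
  vals <- c()
  for (a in idx_a) for (b in idx_b)
    if (a != b) vals <- c(vals, sum(Vn[a, ] * Vn[b, ]))
  mean(vals)
}

# binary prediction matrix without names or reporting attributes
resp <- function(m) {
  attr(m, "n_empty") <- NULL
  unname(m)
}
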