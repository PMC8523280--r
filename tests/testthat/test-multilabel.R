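test_that("restrict_labels intersects a label set with a subset", {
  r <- restrict_labels(c(1, 2, 4), c(1, 2, 3))
  expect_equal(as.integer(r), c(1L, 2L))
  expect_equal(attr(r, "code"), "{1,2}")
  expect_equal(as.integer(restrict_labels(c(2, 3), c(1, 2, 3))), c(2L, 3L))
  empty <- restrict_labels(c(4, 5), c(1, 2, 3))
  expect_length(empty, 0)
  expect_equal(attr(empty, "code"), "{}")
})

test_that("subset sampling is exhaustive without replacement and falls back with", {
  subs <- sample_label_subsets(4, 2, 6, seed = 9)
  expect_length(subs, 6)
  expect_setequal(vapply(subs, paste, character(1), collapse = ","),
                  apply(utils::combn(4, 2), 2, paste, collapse = ","))
  singletons <- sample_label_subsets(5, 1, 5, seed = 1)
  expect_setequal(unlist(singletons), 1:5)
  expect_message(full <- sample_label_subsets(6, 6, 10, seed = 1),
                 "with replacement")
  expect_length(full, 10)
  for (s in full) expect_equal(s, 1:6)
  expect_error(sample_label_subsets(3, 4, 1), "k must")
  expect_error(sample_label_subsets(3, 2, 0), "m_subsets")
  expect_identical(sample_label_subsets(6, 3, 8, seed = 4),
                   sample_label_subsets(6, 3, 8, seed = 4))
})

test_that("vote proportions match hand counting on the three-model example", {
  # subsets {1,2},{2,3},{1,3}; constant predictions {1},{2,3},{3}
  obj <- fake_rakel(list(c(1, 2), c(2, 3), c(1, 3)),
                    c("{1}", "{2,3}", "{3}"), l = 3)
  x <- matrix(0, 1, 2)
  votes <- predict(obj, x, type = "votes")
  expect_equal(unname(votes[1, ]), c(0.5, 0.5, 1.0))
  resp <- predict(obj, x)
  expect_equal(unname(resp[1, ]), c(0, 0, 1))  # strict > 0.5 at the tie
})

test_that("unanimous full or empty predictions give all-or-nothing votes", {
  subsets <- list(c(1, 2), c(2, 3), c(1, 3))
  full <- fake_rakel(subsets, c("{1,2}", "{2,3}", "{1,3}"), l = 3)
  x <- matrix(0, 2, 2)
  expect_true(all(predict(full, x, type = "votes") == 1))
  expect_true(all(predict(full, x) == 1))
  none <- fake_rakel(subsets, c("{}", "{}", "{}"), l = 3)
  expect_true(all(predict(none, x, type = "votes") == 0))
  expect_equal(attr(predict(none, x), "n_empty"), 2L)
})

test_that("rakel predictions equal exhaustive per-label vote counting", {
  base <- base_spec("memorize")
  for (l in 2:4) for (k in seq_len(l)) for (m in c(1, 3, 6)) {
    d <- random_multilabel(n = 10, l = l, seed = l * 100 + k * 10 + m)
    fit <- rakel(d$x, d$y, k = k, m_subsets = m, base = base,
                 seed = k + m)
    votes <- predict(fit, d$x, type = "votes")
    codes <- lapply(fit$models, function(mod) mptype:::predict_base(mod, d$x))
    expected <- oracle_votes(fit$subsets, codes, l, nrow(d$x))
    expect_equal(unname(votes), expected)
    expect_equal(resp(predict(fit, d$x)), (expected > 0.5) + 0)
  }
})

test_that("rakel with k = l and one subset is the label powerset classifier", {
  d <- random_multilabel(n = 12, l = 4, seed = 77)
  fit <- rakel(d$x, d$y, k = 4, m_subsets = 1, base = base_spec("memorize"),
               seed = 3)
  expect_equal(resp(predict(fit, d$x)), unname(d$y) + 0)
})

test_that("rakel with singleton subsets reproduces Binary Relevance", {
  d <- random_multilabel(n = 12, l = 4, seed = 21)
  # one subset per label, exactly
  fit <- rakel(d$x, d$y, k = 1, m_subsets = 4, base = base_spec("memorize"),
               seed = 5)
  expect_setequal(unlist(fit$subsets), 1:4)
  brfit <- br(d$x, d$y, base = base_spec("memorize"))
  expect_equal(resp(predict(fit, d$x)), resp(predict(brfit, d$x)))
})

test_that("prediction is invariant to the stored model order", {
  d <- random_multilabel(n = 8, l = 3, seed = 4)
  fit <- rakel(d$x, d$y, k = 2, m_subsets = 3, base = base_spec("memorize"),
               seed = 8)
  shuffled <- fit
  perm <- c(3, 1, 2)
  shuffled$subsets <- fit$subsets[perm]
  shuffled$models <- fit$models[perm]
  expect_equal(predict(shuffled, d$x, type = "votes"),
               predict(fit, d$x, type = "votes"))
})

test_that("binary relevance trains one model per label and memorizes exactly", {
  d <- random_multilabel(n = 10, l = 6, seed = 15)
  fit <- br(d$x, d$y, base = base_spec("memorize"))
  expect_length(fit$models, 6)
  expect_equal(resp(predict(fit, d$x)), unname(d$y) + 0)
  # permuting label columns permutes per-label outputs identically
  perm <- c(3, 1, 2, 6, 5, 4)
  fit2 <- br(d$x, d$y[, perm], base = base_spec("memorize"))
  expect_equal(resp(predict(fit2, d$x)),
               resp(predict(fit, d$x))[, perm])
})

test_that("constant label columns yield constant predictors, not errors", {
  d <- random_multilabel(n = 6, l = 3, seed = 2)
  y <- d$y
  y[, 2] <- 0L  # never-positive label
  expect_message(fit <- br(d$x, y, base = base_spec("memorize")),
                 "constant predictor")
  expect_true(all(predict(fit, d$x)[, 2] == 0))
})

test_that("dimension mismatches are rejected at prediction time", {
  d <- random_multilabel(n = 6, l = 3, seed = 3)
  fit <- rakel(d$x, d$y, k = 2, m_subsets = 2, base = base_spec("memorize"))
  expect_error(predict(fit, d$x[, 1:2]), "dimension mismatch")
  brfit <- br(d$x, d$y, base = base_spec("memorize"))
  expect_error(predict(brfit, d$x[, 1:2]), "dimension mismatch")
})

test_that("random-forest rakel refits bit-identically under fixed seeds", {
  d <- random_multilabel(n = 30, l = 3, seed = 12)
  base <- base_spec("random_forest", trees = 30)
  f1 <- rakel(d$x, d$y, k = 2, m_subsets = 3, base = base, seed = 6)
  f2 <- rakel(d$x, d$y, k = 2, m_subsets = 3, base = base, seed = 6)
  expect_identical(predict(f1, d$x, type = "votes"),
                   predict(f2, d$x, type = "votes"))
})

test_that("ensembles survive a save/load round trip", {
  d <- random_multilabel(n = 20, l = 3, seed = 9)
  fit <- rakel(d$x, d$y, k = 2, m_subsets = 3,
               base = base_spec("random_forest", trees = 20), seed = 2)
  dir <- withr::local_tempdir()
  save_ensemble(fit, dir, overwrite = TRUE)
  back <- load_ensemble(dir)
  expect_equal(back$subsets, fit$subsets)
  expect_equal(predict(back, d$x, type = "votes"),
               predict(fit, d$x, type = "votes"))
  brfit <- br(d$x, d$y, base = base_spec("memorize"))
  dir2 <- withr::local_tempdir()
  save_ensemble(brfit, dir2, overwrite = TRUE)
  expect_equal(predict(load_ensemble(dir2), d$x), predict(brfit, d$x))
})

test_that("SVM base classifiers train and predict through both ensembles", {
  spec <- synthetic_spec(n_proteins = 80, l = 3, pool_size = 4,
                         background_size = 0, signal = 1,
                         terms_per_protein = c(2, 4), seed = 19,
                         multiplicity_probs = c(0.9, 0.1))
  ds <- generate_dataset(spec)
  suppressMessages(x <- one_hot_encode(ds$annotations))
  y <- unclass(ds$labels)
  for (alg in c("svm_polynomial", "svm_rbf")) {
    fit <- suppressMessages(
      rakel(x, y, k = 3, m_subsets = 3,
            base = base_spec(alg, cost = 2, exponent = 2, gamma = 0.05),
            seed = 4))
    p <- predict(fit, x)
    expect_equal(dim(p), dim(y))
    # perfectly separable one-hot features: high training exact match
    expect_gte(exact_match(y, p), 0.8)
    brfit <- suppressMessages(br(x, y, base = base_spec(alg)))
    expect_equal(dim(predict(brfit, x)), dim(y))
  }
})
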