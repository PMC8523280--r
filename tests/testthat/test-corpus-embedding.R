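test_that("corpus sentences follow the requested token ordering", {
  ann <- annotation_table(list(P1 = c("D2", "D1"), P2 = "D1"))
  expect_equal(build_corpus(ann, "lexicographic"),
               list(P1 = c("D1", "D2"), P2 = "D1"))
  expect_equal(build_corpus(ann, "file-order"),
               list(P1 = c("D2", "D1"), P2 = "D1"))
})

test_that("one-hot encoding matches its definition and conserves counts", {
  ann <- annotation_table(list(P1 = c("D1", "D3"), P2 = c("D2", "DX")))
  suppressMessages(
    m <- one_hot_encode(ann, vocabulary = c("D1", "D2", "D3")))
  expect_equal(unname(m["P1", ]), c(1, 0, 1))
  expect_equal(unname(m["P2", ]), c(0, 1, 0))  # DX out of vocabulary
  # row sums = per-protein in-vocabulary counts; col sums = term frequencies
  expect_equal(unname(rowSums(m)), c(2, 1))
  expect_equal(colSums(m), c(D1 = 1, D2 = 1, D3 = 1))
  expect_warning(suppressMessages(
    one_hot_encode(ann, vocabulary = c("D9"))), "no vocabulary terms")
})

test_that("protein vectors are exact term-vector means", {
  emb <- embedding_table(rbind(D1 = c(1, 0), D2 = c(0, 1), D3 = c(4, 4)))
  ann <- annotation_table(list(A = c("D1", "D2"), B = "D3",
                               C = c("D1", "D2", "D3")))
  pv <- protein_vectors(ann, emb)
  expect_equal(unname(pv["A", ]), c(0.5, 0.5))
  expect_equal(unname(pv["B", ]), c(4, 4))     # mean of one = the vector
  expect_equal(unname(pv["C", ]), c(5, 5) / 3)
})

test_that("out-of-vocabulary terms are skipped; no-hit proteins zeroed", {
  emb <- embedding_table(rbind(D1 = c(2, 2)))
  ann <- annotation_table(list(A = c("D1", "DX"), B = "DY"))
  expect_warning(pv <- protein_vectors(ann, emb), "zero vectors")
  expect_equal(unname(pv["A", ]), c(2, 2))
  expect_equal(unname(pv["B", ]), c(0, 0))
})

test_that("protein vectors stay in the convex hull and commute with row permutation", {
  fx <- generate_fixture_small()
  emb <- train_domain_embeddings(build_corpus(fx$annotations), dimension = 8,
                                 seed = 3)
  pv <- protein_vectors(fx$annotations, emb)
  for (p in fx$annotations$protein_ids) {
    tv <- emb$vectors[fx$annotations$terms[[p]], , drop = FALSE]
    expect_true(all(pv[p, ] >= apply(tv, 2, min) - 1e-12))
    expect_true(all(pv[p, ] <= apply(tv, 2, max) + 1e-12))
  }
  perm <- c(4:12, 1:3)
  ann_perm <- annotation_table(fx$annotations$terms[perm])
  pv_perm <- protein_vectors(ann_perm, emb)
  expect_equal(pv_perm, pv[perm, ], ignore_attr = TRUE)
  expect_equal(rownames(pv_perm), rownames(pv)[perm])
})

test_that("embedding training obeys shape, vocabulary and dimension contracts", {
  corp <- list(s1 = c("a", "b", "c"), s2 = c("a", "b"), s3 = c("c", "d"))
  emb <- train_domain_embeddings(corp, dimension = 50, seed = 7)
  expect_s3_class(emb, "embedding_table")
  expect_equal(emb$dimension, 50L)
  expect_equal(dim(emb$vectors), c(4L, 50L))
  expect_setequal(rownames(emb$vectors), c("a", "b", "c", "d"))
  expect_equal(emb$hyperparameters$architecture, "cbow")
  expect_error(train_domain_embeddings(corp, dimension = 5, min_count = 10),
               "min_count")
})

test_that("embedding training is bit-reproducible under a fixed seed", {
  corp <- build_corpus(generate_fixture_small()$annotations)
  e1 <- train_domain_embeddings(corp, dimension = 12, seed = 42)
  e2 <- train_domain_embeddings(corp, dimension = 12, seed = 42)
  expect_identical(e1$vectors, e2$vectors)
  e3 <- train_domain_embeddings(corp, dimension = 12, seed = 43)
  expect_false(identical(e1$vectors, e3$vectors))
})

test_that("disjoint type pools separate by cosine similarity", {
  spec <- synthetic_spec(n_proteins = 300, l = 6, pool_size = 5,
                         background_size = 0, signal = 1,
                         terms_per_protein = c(2, 5), seed = 11)
  ds <- generate_dataset(spec)
  emb <- train_domain_embeddings(build_corpus(ds$annotations),
                                 dimension = 16, seed = 5)
  V <- emb$vectors
  pool_of <- as.integer(sub("^D(\\d+)\\..*$", "\\1", rownames(V)))
  within <- c(); between <- c()
  for (a in seq_len(nrow(V) - 1)) for (b in (a + 1):nrow(V)) {
    cs <- sum(V[a, ] * V[b, ]) / sqrt(sum(V[a, ]^2) * sum(V[b, ]^2))
    if (pool_of[a] == pool_of[b]) within <- c(within, cs)
    else between <- c(between, cs)
  }
  expect_gt(mean(within), mean(between))
})

test_that("embeddings and features round-trip through their text formats", {
  corp <- build_corpus(generate_fixture_small()$annotations)
  emb <- train_domain_embeddings(corp, dimension = 7, seed = 2)
  f <- withr::local_tempfile()
  write_embeddings(emb, f)
  back <- read_embeddings(f)
  expect_equal(back$vectors, emb$vectors)
  fx <- generate_fixture_small()
  pv <- protein_vectors(fx$annotations, emb)
  g <- withr::local_tempfile()
  write_features(pv, g)
  back2 <- read_features(g)
  expect_identical(attr(back2, "scheme"), "embedding-average")
  expect_equal(back2, pv, ignore_attr = TRUE)
  expect_equal(rownames(back2), rownames(pv))
})
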