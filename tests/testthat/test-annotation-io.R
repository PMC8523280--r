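test_that("pair-per-line annotations parse, deduplicate and keep file order", {
  path <- tmp_tsv(c("# comment", "P1\tD2", "P1\tD1", "P2\tD1", "P1\tD2"))
  ann <- read_annotations(path, dialect = "pairs")
  expect_s3_class(ann, "annotation_table")
  expect_equal(ann$protein_ids, c("P1", "P2"))
  expect_equal(ann$terms, list(P1 = c("D2", "D1"), P2 = "D1"))
})

test_that("terms-list dialect parses comma-separated sentences", {
  path <- tmp_tsv(c("P1\tD1,D2,D1", "P2\tD3"))
  ann <- read_annotations(path, dialect = "lists")
  expect_equal(ann$terms, list(P1 = c("D1", "D2"), P2 = "D3"))
})

test_that("malformed and empty annotation files are rejected with context", {
  bad <- tmp_tsv(c("P1\tD1", "P2\tD2", "P3"))
  expect_error(read_annotations(bad), "line 3")
  empty <- tmp_tsv("# only a comment")
  expect_error(read_annotations(empty), "no annotation records")
})

test_that("label tables encode types as ordered binary columns", {
  path <- tmp_tsv(c("P1\tmultipass", "P2\tGPI-anchor;lipid-anchor"))
  y <- read_labels(path)
  expect_equal(unname(unclass(y)[1, ]), c(0L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(unname(unclass(y)[2, ]), c(1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(colnames(y), membrane_types())
})

test_that("label parsing errors name the offence; duplicates merge by union", {
  expect_error(read_labels(tmp_tsv("P3\tunknown-type")), "unknown-type")
  expect_error(read_labels(tmp_tsv("P1\t;")), "no types")
  y <- read_labels(tmp_tsv(c("P1\tmultipass", "P1\tperipheral")))
  expect_equal(nrow(y), 1L)
  expect_equal(sum(y), 2L)
  expect_equal(colnames(y)[unclass(y)[1, ] == 1L], c("multipass", "peripheral"))
})

test_that("filter_annotated intersects, counts drops, and is idempotent", {
  y <- label_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)),
                    protein_ids = c("P1", "P2", "P3"),
                    label_names = c("a", "b"))
  ann <- annotation_table(list(P1 = "D1", P3 = c("D1", "D2"), P9 = "D3"))
  flt <- filter_annotated(y, ann)
  expect_equal(rownames(flt$labels), c("P1", "P3"))
  expect_equal(flt$annotations$protein_ids, c("P1", "P3"))
  expect_equal(flt$n_dropped, 1L)
  again <- filter_annotated(flt$labels, flt$annotations)
  expect_equal(again$labels, flt$labels)
  expect_equal(again$annotations, flt$annotations)
  expect_equal(again$n_dropped, 0L)
  ann2 <- annotation_table(list(Q1 = "D1"))
  expect_error(filter_annotated(y, ann2), "no protein")
})

test_that("label summaries count types, assignments and multiplicity", {
  y <- read_labels(tmp_tsv(c("P1\tmultipass", "P2\tGPI-anchor;lipid-anchor")))
  s <- summarize_labels(y)
  expect_equal(unname(s$per_type_counts[c("multipass", "GPI-anchor",
                                          "lipid-anchor")]), c(1, 1, 1))
  expect_equal(s$total_assignments, 3L)
  expect_equal(s$multiplicity_counts, c(`1` = 1L, `2` = 1L))
})

test_that("assignment conservation holds on random label matrices", {
  for (seed in 1:5) {
    d <- random_multilabel(40, 5, seed)
    y <- label_matrix(d$y, protein_ids = paste0("P", 1:40),
                      label_names = paste0("t", 1:5))
    s <- summarize_labels(y)
    expect_equal(sum(s$per_type_counts),
                 sum(as.integer(names(s$multiplicity_counts)) *
                       s$multiplicity_counts))
    expect_equal(sum(s$multiplicity_counts), 40L)
  }
})

test_that("annotation and label tables round-trip through their TSV formats", {
  fx <- generate_fixture_small()
  for (dialect in c("pairs", "lists")) {
    f <- withr::local_tempfile()
    write_annotations(fx$annotations, f, dialect = dialect)
    expect_equal(read_annotations(f, dialect = dialect), fx$annotations)
  }
  f <- withr::local_tempfile()
  write_labels(fx$labels, f)
  expect_equal(read_labels(f, label_names = colnames(fx$labels)), fx$labels)
})

test_that("invalid label matrices are rejected", {
  expect_error(label_matrix(rbind(c(1, 2)), "P1", c("a", "b")), "binary")
  expect_error(label_matrix(rbind(c(0, 0)), "P1", c("a", "b")),
               "at least one label")
  expect_error(label_matrix(rbind(c(1, 0), c(0, 1)), c("P1", "P1"),
                            c("a", "b")), "duplicate")
})
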