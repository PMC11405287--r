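test_that("MTX triplet write/read is the identity on random integer matrices", {
  for (seed in 1:5) {
    cm <- random_counts(sample(3:15, 1), sample(3:25, 1), seed = seed)
    dir <- withr::local_tempdir()
    write_count_triplet(cm, dir)
    back <- read_count_triplet(file.path(dir, "matrix.mtx"),
                               file.path(dir, "barcodes.tsv"),
                               file.path(dir, "genes.tsv"))
    expect_identical(dim(back), dim(cm))
    expect_identical(rownames(back), rownames(cm))
    expect_identical(colnames(back), colnames(cm))
    expect_equal(as.matrix(back), as.matrix(cm))
  }
})

test_that("on-disk orientation is resolved against barcode/gene counts", {
  cm <- random_counts(4, 9, seed = 7)
  dir <- withr::local_tempdir()
  # write transposed (genes x cells), the other common dialect
  Matrix::writeMM(Matrix::t(cm), file.path(dir, "matrix.mtx"))
  writeLines(rownames(cm), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(cm), file.path(dir, "genes.tsv"))
  back <- read_count_triplet(file.path(dir, "matrix.mtx"),
                             file.path(dir, "barcodes.tsv"),
                             file.path(dir, "genes.tsv"))
  expect_equal(as.matrix(back), as.matrix(cm))
})

test_that("square ambiguous matrices default to rows = cells with a warning", {
  cm <- random_counts(5, 5, seed = 3)
  dir <- withr::local_tempdir()
  write_count_triplet(cm, dir)
  expect_warning(
    back <- read_count_triplet(file.path(dir, "matrix.mtx"),
                               file.path(dir, "barcodes.tsv"),
                               file.path(dir, "genes.tsv")),
    "rows = cells")
  expect_equal(as.matrix(back), as.matrix(cm))
})

test_that("empty (0-cell) matrices roundtrip and invalid matrices are rejected", {
  empty <- as_count_matrix(matrix(0L, 0, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))),
                           cell_ids = character(0))
  dir <- withr::local_tempdir()
  write_count_triplet(empty, dir)
  back <- read_count_triplet(file.path(dir, "matrix.mtx"),
                             file.path(dir, "barcodes.tsv"),
                             file.path(dir, "genes.tsv"))
  expect_identical(dim(back), c(0L, 3L))

  m <- matrix(1, 2, 2, dimnames = list(c("c1", "c2"), c("g", "g")))
  expect_error(as_count_matrix(m), "duplicate gene")
  m2 <- matrix(c(1, -1, 0, 2), 2, 2,
               dimnames = list(c("c1", "c2"), c("g1", "g2")))
  expect_error(as_count_matrix(m2), "non-negative")
  m3 <- matrix(c(1, 0.5, 0, 2), 2, 2,
               dimnames = list(c("c1", "c2"), c("g1", "g2")))
  expect_error(as_count_matrix(m3), "integer")
})

test_that("metadata validation reports missing fields, vocabulary and duplicates", {
  md <- conformant_metadata(5)
  rep0 <- validate_metadata(md)
  expect_true(rep0$passed)
  expect_identical(nrow(rep0$errors), 0L)

  md1 <- md[, setdiff(names(md), "donor_sex")]
  rep1 <- validate_metadata(md1)
  expect_false(rep1$passed)
  expect_identical(rep1$errors$type, "missing_field")
  expect_identical(rep1$errors$field, "donor_sex")

  md2 <- md
  md2$if_patient[2] <- "maybe"
  rep2 <- validate_metadata(md2)
  expect_false(rep2$passed)
  expect_identical(rep2$errors$type, "vocabulary")
  expect_identical(rep2$errors$field, "if_patient")
  expect_identical(rep2$errors$value, "maybe")

  md3 <- md
  md3$cell_ID[2] <- md3$cell_ID[1]
  expect_true("duplicate_cell_ID" %in% validate_metadata(md3)$errors$type)
})

test_that("age normalization covers the full documented grammar", {
  expect_equal(normalize_age("6 GW", "fetal"),
               data.frame(value = 6, unit = "gestational_week"))
  expect_equal(normalize_age("3 months", "adult"),
               data.frame(value = 3, unit = "month"))
  expect_equal(normalize_age("D60", "organoid"),
               data.frame(value = 60, unit = "culture_day"))
  # bare numbers take the sample-type default unit
  expect_equal(normalize_age("47", "adult")$unit, "year")
  expect_equal(normalize_age("12", "fetal")$unit, "gestational_week")
  expect_equal(normalize_age("30", "organoid")$unit, "culture_day")
  # months >= 12 are promoted to years so month implies value < 12
  expect_equal(normalize_age("18 months", "adult"),
               data.frame(value = 1.5, unit = "year"))
  # missing marker and rejection of everything else
  expect_true(is.na(normalize_age("N/A", "adult")$value))
  expect_error(normalize_age("six weeks old", "adult"), "six weeks old")
  expect_error(normalize_age("-3", "adult"))
})

test_that("ortholog merge keeps shared 1:1 pairs and renames into A's namespace", {
  a <- annotated_dataset(random_counts(4, 3, seed = 1))
  bmat <- random_counts(3, 3, seed = 2)
  colnames(bmat) <- c("m1", "m2", "m3")
  rownames(bmat) <- paste0("bc", 1:3)
  b <- annotated_dataset(bmat)
  # B lacks the third mapped gene
  tab <- data.frame(human = c("g001", "g002", "g003"),
                    mouse = c("m1", "m2", "mX"))
  merged <- merge_orthologs(a, b, tab, "human", "mouse")
  expect_identical(sort(colnames(merged$counts)), c("g001", "g002"))
  expect_identical(nrow(merged$counts), 7L)
  expect_identical(as.vector(table(merged$metadata$species)[c("human", "mouse")]),
                   c(4L, 3L))
  expect_equal(as.vector(merged$counts["bc1", "g001"]),
               as.vector(bmat["bc1", "m1"]))
})

test_that("non-1:1 ortholog rows are dropped before joining", {
  a <- annotated_dataset(random_counts(3, 4, seed = 3))
  b <- annotated_dataset(random_counts(3, 4, seed = 4))
  # g001 maps to two targets, g003->g003 and g004->g004 clean
  tab <- data.frame(a = c("g001", "g001", "g003", "g004"),
                    b = c("g001", "g002", "g003", "g004"))
  merged <- suppressMessages(merge_orthologs(a, b, tab))
  expect_identical(sort(colnames(merged$counts)), c("g003", "g004"))
  # brute-force: the kept set is exactly the rows unique in both columns
  keep <- with(tab, !(a %in% a[duplicated(a)] | b %in% b[duplicated(b)]))
  expect_identical(sort(colnames(merged$counts)), sort(tab$a[keep]))
})

test_that("ortholog merge is invariant to gene column order and bounded in size", {
  a <- annotated_dataset(random_counts(4, 6, seed = 5))
  b <- annotated_dataset(random_counts(3, 6, seed = 6))
  tab <- data.frame(a = colnames(a$counts), b = colnames(b$counts))
  m1 <- merge_orthologs(a, b, tab)
  perm <- sample(6)
  a2 <- annotated_dataset(a$counts[, perm])
  m2 <- merge_orthologs(a2, b, tab)
  expect_lte(ncol(m1$counts), min(ncol(a$counts), ncol(b$counts)))
  expect_equal(as.matrix(m1$counts[, sort(colnames(m1$counts))]),
               as.matrix(m2$counts[, sort(colnames(m2$counts))]))
  # identity merge doubles the cells, keeps the gene set
  dup <- merge_orthologs(a, a, data.frame(colnames(a$counts),
                                          colnames(a$counts)))
  expect_identical(nrow(dup$counts), 2L * nrow(a$counts))
  expect_setequal(colnames(dup$counts), colnames(a$counts))
})

test_that("label trees roundtrip through JSON and validate label consistency", {
  tree <- label_tree(list(Neuron = c("Excitatory", "Inhibitory"),
                          Glia = c("Astrocyte", "Oligodendrocyte", "OPC")))
  path <- withr::local_tempfile(fileext = ".json")
  write_label_tree(tree, path)
  back <- read_label_tree(path)
  expect_equal(back$classes, tree$classes)
  expect_error(label_tree(list(A = c("x", "y"), B = "x")), "duplicate subtype")
  expect_silent(check_labels_against_tree(tree, c("Neuron", NA),
                                          c("Excitatory", NA)))
  expect_error(check_labels_against_tree(tree, "Neuron", "Astrocyte"),
               "outside")
})

test_that("dataset directories roundtrip counts, metadata, labels and scores", {
  sim <- small_atlas(classes = 2, subtypes = 2, cells = 15, genes = 50,
                     seed = 11)
  ds <- sim$dataset
  ds$doublet_score <- runif(nrow(ds$counts))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(as.matrix(back$counts), as.matrix(ds$counts))
  expect_identical(back$labels1, ds$labels1)
  expect_identical(back$labels2, ds$labels2)
  expect_equal(back$doublet_score, ds$doublet_score)
  expect_identical(back$metadata$sample_ID, ds$metadata$sample_ID)
})
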