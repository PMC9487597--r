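test_that("count matrices round-trip through mtx and csv exactly", {
  vals <- matrix(c(0, 1, 2, 0, 5, 5), nrow = 3, byrow = TRUE)
  cm <- count_matrix(vals, c("gA", "gB", "gC"), c("c1", "c2"),
                     platform = "SS2")
  expect_equal(unname(as.matrix(cm$values)), vals)

  mtx_dir <- withr::local_tempdir()
  write_counts(cm, file.path(mtx_dir, "ds"), format = "mtx")
  back <- read_counts(file.path(mtx_dir, "ds"), platform = "SS2")
  expect_equal(as.matrix(back$values), as.matrix(cm$values),
               ignore_attr = TRUE)
  expect_identical(back$gene_ids, cm$gene_ids)
  expect_identical(back$cell_ids, cm$cell_ids)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_counts(cm, csv, format = "csv")
  back2 <- read_counts(csv, platform = "SS2")
  expect_equal(unname(as.matrix(back2$values)), vals)
})

test_that("an empty Matrix Market header yields an all-zero matrix", {
  dirn <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "10 4 0"), file.path(dirn, "matrix.mtx"))
  writeLines(sprintf("g%d", 1:10), file.path(dirn, "genes.tsv"))
  writeLines(sprintf("c%d", 1:4), file.path(dirn, "barcodes.tsv"))
  cm <- read_counts(file.path(dirn, "matrix.mtx"))
  expect_equal(dim(cm$values), c(10L, 4L))
  expect_equal(sum(cm$values), 0)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(count_matrix(matrix(-1), "g1", "c1"), "negative")
  expect_error(count_matrix(matrix(0, 2, 1), c("g", "g"), "c1"),
               "duplicate gene ids.*g")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2", "g1,3,-2"), csv)
  expect_error(read_counts(csv), "invalid count.*g1")
  expect_error(read_counts("/nonexistent/file.csv"), "does not exist")
})

test_that("lognormalize matches the closed form and is monotone per cell", {
  cm <- count_matrix(matrix(c(10, 90, 0, 30, 50, 20), nrow = 3),
                     c("g1", "g2", "g3"), c("c1", "c2"))
  nm <- lognormalize(cm, scale_factor = 1e4)
  # X=10, colsum=100 -> ln(1 + 10/100*1e4) = ln(1001)
  expect_equal(nm$values[1, 1], log(1001))
  expect_equal(nm$values[3, 1], 0) # zero count stays zero
  # monotone within each cell
  for (j in 1:2) {
    ord_counts <- order(as.matrix(cm$values)[, j])
    expect_false(is.unsorted(as.matrix(nm$values)[ord_counts, j]))
  }
  zero_cell <- count_matrix(matrix(c(1, 0, 0, 0), 2), c("g1", "g2"),
                            c("ok", "empty"))
  expect_error(lognormalize(zero_cell), "empty")
})

test_that("scale_genes gives unit variance and is idempotent", {
  nm <- list(values = matrix(c(0, 2, 4, 5, 5, 5, 1, 7, 4), nrow = 3,
                             byrow = TRUE),
             gene_ids = c("g1", "g2", "g3"), cell_ids = c("a", "b", "c"),
             platform = "x")
  sm <- scale_genes(nm)
  expect_equal(unname(apply(sm$values[c(1, 3), ], 1, sd)), c(1, 1))
  expect_equal(unname(sm$values[2, ]), c(0, 0, 0)) # constant gene -> 0
  # default scaling is the classical z-score: centered, unit variance
  expect_equal(unname(sm$values[1, ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(sm$values)), c(0, 0, 0), tolerance = 1e-12)
  # [0, 2] -> +-1/sqrt(2) with the sample sd
  nm2 <- list(values = matrix(c(0, 2), 1), gene_ids = "g",
              cell_ids = c("a", "b"), platform = "x")
  expect_equal(unname(scale_genes(nm2)$values[1, ]),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # variance-only scaling on request
  expect_equal(unname(scale_genes(nm2, center = FALSE)$values[1, ]),
               c(0, sqrt(2)), tolerance = 1e-12)
  # idempotence: scaling an already unit-variance matrix changes nothing
  again <- scale_genes(list(values = sm$values, gene_ids = sm$gene_ids,
                            cell_ids = sm$cell_ids, platform = "x"))
  expect_equal(again$values, sm$values, tolerance = 1e-8)
})

test_that("select_hvg ranks a bimodal gene first, deterministically", {
  set.seed(7)
  n <- 60
  # one bimodal gene, one mirror-image compensator keeping totals equal,
  # all remaining genes constant
  counts <- matrix(5L, nrow = 20, ncol = n)
  counts[1, ] <- rep(c(0L, 40L), each = n / 2) # bimodal across populations
  counts[2, ] <- rep(c(40L, 0L), each = n / 2)
  cm <- count_matrix(counts, sprintf("g%02d", 1:20), sprintf("c%02d", 1:n))
  nm <- lognormalize(cm)
  for (method in c("vst", "dispersion")) {
    expect_identical(select_hvg(nm, 1, method = method), "g01")
  }
  # invariant to cell order
  perm <- sample(n)
  nm_perm <- lognormalize(count_matrix(counts[, perm],
                                       sprintf("g%02d", 1:20),
                                       sprintf("c%02d", 1:n)[perm]))
  expect_identical(select_hvg(nm, 5), select_hvg(nm_perm, 5))
  # n larger than the gene count warns and returns everything
  expect_warning(all_genes <- select_hvg(nm, 100), "returning all")
  expect_setequal(all_genes, sprintf("g%02d", 1:20))
})

test_that("hvg ties break towards the lexicographically smaller gene id", {
  counts <- matrix(c(0, 4, 0, 4, 0, 4, 0, 4, 2, 2, 2, 2), nrow = 3,
                   byrow = TRUE) # rows 1 and 2 identical
  cm <- count_matrix(counts, c("gB", "gA", "gC"), sprintf("c%d", 1:4))
  got <- select_hvg(lognormalize(cm), 2, method = "dispersion")
  expect_identical(got, c("gA", "gB"))
})

test_that("shared_hvg intersects, sorts, and rejects disjoint lists", {
  expect_identical(shared_hvg(c("A", "B", "C"), c("C", "B", "D")),
                   c("B", "C"))
  expect_identical(shared_hvg(c("x", "y"), c("y", "x")), c("x", "y"))
  expect_error(shared_hvg(c("A"), c("B")), "n_hvg")
})
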