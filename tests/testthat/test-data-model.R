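test_that("dataset construction validates its invariants", {
  counts <- matrix(c(1, 0, 2, 3, 0, 5), 3, 2)
  ds <- gene_expression_dataset(counts, batch = c(0, 0, 1))
  expect_equal(ds$n_cells, 3)
  expect_equal(ds$n_genes, 2)
  expect_equal(ds$n_batches, 2)
  expect_error(gene_expression_dataset(matrix(-1, 1, 1)), "negative")
  expect_error(gene_expression_dataset(matrix(1.5, 1, 1)), "non-integer")
  expect_error(gene_expression_dataset(counts, batch = c(0, 1)), "mismatch")
  expect_error(gene_expression_dataset(counts, gene_ids = c("a", "a")), "unique")
  expect_error(gene_expression_dataset(counts, batch = c(0, 0, 5), n_batches = 2),
               "out of range")
})

test_that("CSV and Matrix Market round trips preserve the dataset", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(simulation_spec(n_cells = 40, n_genes = 12,
                                          n_batches = 2, n_labels = 2, seed = 3))
  ds <- sim$dataset
  write_dataset(ds, dir)
  back <- read_dataset(file.path(dir, "counts.mtx"), file.path(dir, "cells.csv"),
                       file.path(dir, "genes.csv"))
  expect_equal(back$counts, ds$counts, ignore_attr = TRUE)
  expect_equal(back$batch, ds$batch)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$gene_ids, ds$gene_ids)

  # dense CSV with header, batch column in metadata
  cpath <- file.path(dir, "dense.csv")
  utils::write.csv(as.data.frame(ds$counts[1:3, ]) |>
                     stats::setNames(ds$gene_ids), cpath, row.names = FALSE)
  mpath <- file.path(dir, "meta3.csv")
  utils::write.csv(data.frame(cell_id = 1:3, batch = c(0, 0, 1)), mpath,
                   row.names = FALSE)
  d2 <- read_dataset(cpath, mpath)
  expect_equal(d2$n_batches, 2)
  expect_equal(d2$counts, ds$counts[1:3, ], ignore_attr = TRUE)

  # dimension mismatch between counts and metadata is a load error
  expect_error(read_dataset(file.path(dir, "counts.mtx"), mpath), "mismatch")

  # a negative entry is rejected at validation
  neg <- Matrix::Matrix(matrix(c(1, -1, 0, 2), 2, 2), sparse = TRUE)
  npath <- file.path(dir, "neg.mtx")
  Matrix::writeMM(neg, npath)
  utils::write.csv(data.frame(cell_id = 1:2, batch = c(0, 0)),
                   file.path(dir, "meta2.csv"), row.names = FALSE)
  expect_error(read_dataset(npath, file.path(dir, "meta2.csv")), "negative")
})

test_that("concatenation stacks cells, offsets batches and aligns genes", {
  g <- paste0("g", 1:5)
  a <- gene_expression_dataset(matrix(0:9, 2, 5), gene_ids = g)
  b <- gene_expression_dataset(matrix(9:0, 2, 5), gene_ids = g)
  ab <- concat_datasets(a, b)
  expect_equal(ab$n_cells, 4)
  expect_equal(ab$batch, c(0L, 0L, 1L, 1L))
  expect_equal(ab$n_batches, 2L)

  # permuting one dataset's gene order must not change the result
  perm <- c(4, 2, 5, 1, 3)
  b_perm <- gene_expression_dataset(b$counts[, perm], gene_ids = g[perm])
  ab2 <- concat_datasets(a, b_perm)
  expect_equal(ab2$counts, ab$counts)
  expect_equal(ab2$gene_ids, ab$gene_ids)

  c_ds <- gene_expression_dataset(matrix(1, 2, 2), gene_ids = c("x1", "x2"))
  expect_error(concat_datasets(a, c_ds), "intersection")
  expect_error(concat_datasets(a), "at least two")
})

test_that("dispersion-based gene selection matches direct recomputation", {
  # constant gene has dispersion 0 and is never selected over a variable one
  counts <- cbind(A = rep(5, 20), B = rpois(20, 5))
  ds <- gene_expression_dataset(counts, gene_ids = c("A", "B"))
  expect_equal(select_genes_by_dispersion(ds, 1), "B")

  set.seed(42)
  sim1 <- simulate_dataset(simulation_spec(n_cells = 80, n_genes = 30,
                                           n_batches = 1, n_labels = 2, seed = 5))
  sim2 <- simulate_dataset(simulation_spec(n_cells = 80, n_genes = 30,
                                           n_batches = 1, n_labels = 2, seed = 6))
  got <- select_genes_by_dispersion(list(sim1$dataset, sim2$dataset), 10)
  brute <- function(ds, g) {
    disp <- apply(ds$counts, 2, function(x) if (mean(x) > 0) var(x) / mean(x) else 0)
    ds$gene_ids[order(-disp, ds$gene_ids)][1:g]
  }
  expect_setequal(got, union(brute(sim1$dataset, 10), brute(sim2$dataset, 10)))
  expect_equal(got, sort(got))            # deterministic sorted order
  expect_equal(anyDuplicated(got), 0L)

  # invariant to cell order
  shuf <- subset_cells(sim1$dataset, sample(sim1$dataset$n_cells))
  expect_equal(select_genes_by_dispersion(shuf, 10),
               select_genes_by_dispersion(sim1$dataset, 10))
})

test_that("disjoint per-dataset top sets union to their combined size", {
  # construct two datasets whose top-3 dispersion genes are disjoint by design
  set.seed(8)
  n <- 60
  mk <- function(hot) {
    X <- matrix(rpois(n * 6, 2), n, 6)
    X[, hot] <- rpois(n * 3, 2) * rbinom(n * 3, 1, 0.3) * 8
    gene_expression_dataset(X, gene_ids = paste0("g", 1:6))
  }
  d1 <- mk(1:3); d2 <- mk(4:6)
  u <- select_genes_by_dispersion(list(d1, d2), 3)
  expect_length(u, 6)
})

test_that("CITE-seq protein normalization splits the two modes at their midpoint", {
  set.seed(1)
  x <- c(rnorm(150, 2, 0.1), rnorm(150, 10, 0.1))
  out <- normalize_cite_proteins(cbind(p1 = x))
  mid <- attr(out, "midpoint")[["p1"]]
  expect_lt(abs(mid - 6), 0.5)
  expect_true(all(out[x < 3, 1] == 0))            # low mode clamps to zero
  expect_true(all(out >= 0))
  # both mixture means shift with the data, so the midpoint-subtracted
  # output is invariant under a global shift
  out2 <- normalize_cite_proteins(cbind(p1 = x + 5))
  expect_equal(out2[, 1], out[, 1], tolerance = 0.05)
  expect_equal(attr(out2, "midpoint")[["p1"]], mid + 5, tolerance = 0.2)
  expect_error(normalize_cite_proteins(cbind(q = rep(3, 10))), "q")
})

test_that("transcript-length normalization divides by relative length and floors", {
  X <- matrix(c(10, 7, 4, 9), 2, 2)
  expect_equal(normalize_smartseq2_lengths(X, c(100, 100)), X)   # equal lengths
  # one gene at twice the mean length is halved
  out <- normalize_smartseq2_lengths(matrix(c(10, 8), 1, 2), c(300, 100))
  expect_equal(out[1, 1], floor(10 / (300 / 200)))
  expect_equal(out[1, 2], floor(8 / (100 / 200)))
  set.seed(2)
  X <- matrix(rpois(50, 20), 10, 5)
  len <- runif(5, 50, 500)
  expect_equal(normalize_smartseq2_lengths(X, len),
               floor(sweep(X, 2, len / mean(len), "/")))
  expect_true(all(normalize_smartseq2_lengths(X, len) >= 0))
  expect_error(normalize_smartseq2_lengths(X, c(-1, 1, 1, 1, 1)), "positive")
})

test_that("signature and hierarchy containers enforce their invariants", {
  expect_error(signature_def("T", positive = "CD3", negative = "CD3"), "overlap")
  expect_error(signature_def("T"), "no genes")
  h <- label_hierarchy(c(0, 0, 1, 1))
  expect_equal(h$n_fine, 4)
  expect_equal(h$n_coarse, 2)
  expect_error(label_hierarchy(c(0, NA)), "parent")
})
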