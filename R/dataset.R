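#' Construct a gene expression dataset
#'
#' The basic container used throughout the package: a cells x genes matrix of
#' non-negative integer counts together with a per-cell batch index and
#' (optionally) per-cell labels at one or two levels of a cell-type taxonomy.
#'
#' @param counts A cells x genes matrix (base matrix or `Matrix` sparse matrix)
#'   of non-negative integers.  Stored densely; rows are cells, columns genes.
#' @param batch Integer vector of length `n_cells` with values in
#'   `0..(n_batches-1)`, the dataset/batch of origin of each cell.  Defaults to
#'   a single batch.
#' @param labels Optional integer vector of per-cell label ids in
#'   `0..(n_labels-1)`; `NA` marks an unlabeled cell.
#' @param labels_coarse Optional integer vector of coarse-level label ids
#'   (`NA` allowed), used with a [label_hierarchy()].
#' @param gene_ids Character vector of unique gene identifiers (one per
#'   column).  Defaults to `gene1..geneG`.
#' @param cell_ids Optional character vector of unique cell identifiers.
#' @param label_names Optional character vector naming the label ids.
#' @param n_batches Total number of batches; defaults to `max(batch) + 1`.
#'
#' @return An object of class `gene_expression_dataset`: a list with elements
#'   `counts`, `batch`, `labels`, `labels_coarse`, `gene_ids`, `cell_ids`,
#'   `label_names`, `n_batches`, `n_cells`, `n_genes`.
#' @export
gene_expression_dataset <- function(counts, batch = NULL, labels = NULL,
                                    labels_coarse = NULL, gene_ids = NULL,
                                    cell_ids = NULL, label_names = NULL,
                                    n_batches = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  g <- ncol(counts)
  if (is.null(batch)) batch <- rep(0L, n)
  batch <- as.integer(batch)
  if (is.null(n_batches)) n_batches <- max(batch) + 1L
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(g))
  if (!is.null(labels)) labels <- as.integer(labels)
  if (!is.null(labels_coarse)) labels_coarse <- as.integer(labels_coarse)
  ds <- structure(list(
    counts = counts, batch = batch, labels = labels,
    labels_coarse = labels_coarse, gene_ids = as.character(gene_ids),
    cell_ids = cell_ids, label_names = label_names,
    n_batches = as.integer(n_batches), n_cells = n, n_genes = g
  ), class = "gene_expression_dataset")
  validate_dataset(ds)
  ds
}

#' @export
print.gene_expression_dataset <- function(x, ...) {
  cat(sprintf("gene_expression_dataset: %d cells x %d genes, %d batch(es)\n",
              x$n_cells, x$n_genes, x$n_batches))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d observed / %d cells (%d classes)\n",
                sum(!is.na(x$labels)), x$n_cells,
                length(unique(stats::na.omit(x$labels)))))
  }
  if (!is.null(x$labels_coarse)) {
    cat(sprintf("  coarse labels: %d observed\n", sum(!is.na(x$labels_coarse))))
  }
  invisible(x)
}

validate_dataset <- function(ds) {
  cn <- ds$counts
  if (length(ds$batch) != nrow(cn))
    stop("dimension mismatch: ", nrow(cn), " cells in counts but ",
         length(ds$batch), " batch entries")
  if (any(!is.finite(cn)))
    stop("counts contain non-finite entries")
  if (any(cn < 0))
    stop("counts contain negative entries")
  if (any(cn != floor(cn)))
    stop("counts contain non-integer entries")
  if (any(ds$batch < 0L | ds$batch >= ds$n_batches))
    stop("batch index out of range [0, ", ds$n_batches, ")")
  if (!is.null(ds$labels)) {
    if (length(ds$labels) != nrow(cn))
      stop("labels length does not match number of cells")
    obs <- ds$labels[!is.na(ds$labels)]
    if (length(obs) && any(obs < 0L))
      stop("negative label id")
  }
  if (anyDuplicated(ds$gene_ids))
    stop("gene_ids are not unique")
  if (length(ds$gene_ids) != ncol(cn))
    stop("gene_ids length does not match number of genes")
  invisible(TRUE)
}

#' Number of observed (annotated) label classes in a dataset
#' @param ds A [gene_expression_dataset()].
#' @return Integer count of distinct non-missing label ids.
#' @export
n_observed_labels <- function(ds) {
  if (is.null(ds$labels)) return(0L)
  length(unique(stats::na.omit(ds$labels)))
}

#' Read a dataset from a counts file plus a cell metadata file
#'
#' The counts file is either Matrix Market (`.mtx`, cells x genes) or a
#' delimited dense text matrix with a header row of gene ids.  The metadata
#' file is a CSV with one row per cell and columns `cell_id`, `batch` and
#' optionally `label` and `label_coarse` (empty/NA meaning unlabeled).
#'
#' @param counts_path Path to the counts matrix.
#' @param meta_path Path to the per-cell metadata CSV.
#' @param gene_path Optional path to a gene metadata CSV with columns
#'   `gene_id` and optionally `transcript_length`.
#' @return A [gene_expression_dataset()]; transcript lengths, when present,
#'   are attached as attribute `transcript_length`.
#' @export
read_dataset <- function(counts_path, meta_path, gene_path = NULL) {
  if (grepl("\\.mtx$", counts_path, ignore.case = TRUE)) {
    counts <- as.matrix(Matrix::readMM(counts_path))
    gene_ids <- NULL
  } else {
    tab <- utils::read.csv(counts_path, check.names = FALSE)
    counts <- as.matrix(tab)
    gene_ids <- colnames(tab)
  }
  meta <- utils::read.csv(meta_path)
  if (nrow(meta) != nrow(counts))
    stop("dimension mismatch: counts has ", nrow(counts),
         " cells but metadata has ", nrow(meta), " rows")
  if (!"batch" %in% names(meta)) stop("metadata must have a 'batch' column")
  labels <- if ("label" %in% names(meta)) suppressWarnings(as.integer(meta$label)) else NULL
  coarse <- if ("label_coarse" %in% names(meta)) suppressWarnings(as.integer(meta$label_coarse)) else NULL
  lengths <- NULL
  if (!is.null(gene_path)) {
    gtab <- utils::read.csv(gene_path)
    if (nrow(gtab) != ncol(counts))
      stop("gene metadata rows do not match number of genes")
    gene_ids <- as.character(gtab$gene_id)
    if ("transcript_length" %in% names(gtab)) lengths <- gtab$transcript_length
  }
  ds <- gene_expression_dataset(
    counts, batch = meta$batch, labels = labels, labels_coarse = coarse,
    gene_ids = gene_ids,
    cell_ids = if ("cell_id" %in% names(meta)) as.character(meta$cell_id) else NULL
  )
  if (!is.null(lengths)) attr(ds, "transcript_length") <- lengths
  ds
}

#' Write a dataset as Matrix Market counts plus metadata CSVs
#'
#' Inverse of [read_dataset()]: writes `counts.mtx`, `cells.csv` and
#' `genes.csv` under `dir`.
#'
#' @param ds A [gene_expression_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "counts.mtx")
  Matrix::writeMM(Matrix::Matrix(ds$counts, sparse = TRUE), cpath)
  meta <- data.frame(
    cell_id = if (is.null(ds$cell_ids)) paste0("cell", seq_len(ds$n_cells)) else ds$cell_ids,
    batch = ds$batch
  )
  if (!is.null(ds$labels)) meta$label <- ds$labels
  if (!is.null(ds$labels_coarse)) meta$label_coarse <- ds$labels_coarse
  mpath <- file.path(dir, "cells.csv")
  utils::write.csv(meta, mpath, row.names = FALSE, na = "")
  gtab <- data.frame(gene_id = ds$gene_ids)
  if (!is.null(attr(ds, "transcript_length")))
    gtab$transcript_length <- attr(ds, "transcript_length")
  gpath <- file.path(dir, "genes.csv")
  utils::write.csv(gtab, gpath, row.names = FALSE)
  invisible(c(counts = cpath, cells = mpath, genes = gpath))
}

#' Concatenate datasets over their shared genes
#'
#' Cells are stacked and batch indices offset so that batches from different
#' inputs remain distinct.  Genes are restricted to the intersection of the
#' gene-id sets, in sorted gene-id order for determinism.
#'
#' @param ... Two or more [gene_expression_dataset()] objects, or a single
#'   list of them.
#' @return A combined [gene_expression_dataset()].
#' @export
concat_datasets <- function(...) {
  dss <- list(...)
  if (length(dss) == 1L && !inherits(dss[[1]], "gene_expression_dataset"))
    dss <- dss[[1]]
  if (length(dss) < 2L) stop("need at least two datasets")
  shared <- Reduce(intersect, lapply(dss, function(d) d$gene_ids))
  if (length(shared) == 0L) stop("empty gene intersection across datasets")
  shared <- sort(shared)
  offset <- 0L
  counts <- list(); batch <- list(); labels <- list(); coarse <- list()
  cells <- list()
  any_lab <- any(vapply(dss, function(d) !is.null(d$labels), logical(1)))
  any_coarse <- any(vapply(dss, function(d) !is.null(d$labels_coarse), logical(1)))
  for (d in dss) {
    idx <- match(shared, d$gene_ids)
    counts[[length(counts) + 1L]] <- d$counts[, idx, drop = FALSE]
    batch[[length(batch) + 1L]] <- d$batch + offset
    offset <- offset + d$n_batches
    labels[[length(labels) + 1L]] <-
      if (is.null(d$labels)) rep(NA_integer_, d$n_cells) else d$labels
    coarse[[length(coarse) + 1L]] <-
      if (is.null(d$labels_coarse)) rep(NA_integer_, d$n_cells) else d$labels_coarse
    cells[[length(cells) + 1L]] <-
      if (is.null(d$cell_ids)) rep(NA_character_, d$n_cells) else d$cell_ids
  }
  cid <- unlist(cells)
  gene_expression_dataset(
    do.call(rbind, counts), batch = unlist(batch),
    labels = if (any_lab) unlist(labels) else NULL,
    labels_coarse = if (any_coarse) unlist(coarse) else NULL,
    gene_ids = shared, n_batches = offset,
    cell_ids = if (!anyNA(cid) && !anyDuplicated(cid)) cid else NULL,
    label_names = dss[[1]]$label_names
  )
}

#' Select highly variable genes by dispersion
#'
#' Within each dataset every gene is ranked by its dispersion, the
#' variance-to-mean ratio of raw counts across cells (0/0 defined as 0); the
#' top `g_per_dataset` genes per dataset are taken and the union returned in
#' sorted gene-id order.  All-zero genes have dispersion 0 and are never
#' selected ahead of a gene with positive dispersion.
#'
#' @param datasets A [gene_expression_dataset()] or list of them.
#' @param g_per_dataset Number of top-dispersion genes per dataset.
#' @return Character vector: union of selected gene ids, sorted.
#' @export
select_genes_by_dispersion <- function(datasets, g_per_dataset) {
  if (inherits(datasets, "gene_expression_dataset")) datasets <- list(datasets)
  stopifnot(g_per_dataset >= 1)
  picked <- character(0)
  for (d in datasets) {
    disp <- gene_dispersion(d$counts)
    g <- min(g_per_dataset, d$n_genes)
    # ties broken by gene-id order so the selection is reproducible
    ord <- order(-disp, d$gene_ids)
    picked <- c(picked, d$gene_ids[ord[seq_len(g)]])
  }
  sort(unique(picked))
}

gene_dispersion <- function(counts) {
  m <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  ifelse(m > 0, v / m, 0)
}

#' Restrict a dataset to a gene subset
#' @param ds A [gene_expression_dataset()].
#' @param gene_ids Genes to keep (must all be present); kept in the given order.
#' @return A [gene_expression_dataset()] over the subset.
#' @export
subset_genes <- function(ds, gene_ids) {
  idx <- match(gene_ids, ds$gene_ids)
  if (anyNA(idx))
    stop("genes not in dataset: ", paste(gene_ids[is.na(idx)], collapse = ", "))
  gene_expression_dataset(ds$counts[, idx, drop = FALSE], batch = ds$batch,
                          labels = ds$labels, labels_coarse = ds$labels_coarse,
                          gene_ids = gene_ids, cell_ids = ds$cell_ids,
                          label_names = ds$label_names, n_batches = ds$n_batches)
}

#' Restrict a dataset to a cell subset
#' @param ds A [gene_expression_dataset()].
#' @param idx Integer or logical index over cells.
#' @return A [gene_expression_dataset()] over the selected cells.
#' @export
subset_cells <- function(ds, idx) {
  gene_expression_dataset(ds$counts[idx, , drop = FALSE], batch = ds$batch[idx],
                          labels = ds$labels[idx], labels_coarse = ds$labels_coarse[idx],
                          gene_ids = ds$gene_ids,
                          cell_ids = ds$cell_ids[idx],
                          label_names = ds$label_names, n_batches = ds$n_batches)
}

#' Define a marker-gene signature
#'
#' A signed gene set for one cell-type label: genes expected to be expressed
#' (`positive`) and genes expected to be absent (`negative`).
#'
#' @param label Label name the signature identifies.
#' @param positive,negative Character vectors of gene ids; must be disjoint
#'   and jointly non-empty.
#' @return An object of class `signature_def`.
#' @export
signature_def <- function(label, positive = character(0), negative = character(0)) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  if (length(intersect(positive, negative)))
    stop("positive and negative gene sets overlap")
  if (length(positive) + length(negative) == 0L)
    stop("signature has no genes")
  structure(list(label = label, positive = positive, negative = negative),
            class = "signature_def")
}

#' Read signature definitions from CSV
#'
#' Expects columns `label`, `gene_id`, `sign` (+1/-1).
#' @param path CSV file path.
#' @return A list of [signature_def()] objects, one per label.
#' @export
read_signatures <- function(path) {
  tab <- utils::read.csv(path)
  lapply(split(tab, tab$label), function(s) {
    signature_def(s$label[1], positive = s$gene_id[s$sign > 0],
                  negative = s$gene_id[s$sign < 0])
  })
}

#' Define a two-level label hierarchy
#'
#' @param fine_to_coarse Integer vector: entry `i` is the coarse label id
#'   (0-based) of fine label `i - 1`.  Must be total on the fine label range.
#' @param fine_names,coarse_names Optional name vectors.
#' @return An object of class `label_hierarchy` with fields `fine_to_coarse`,
#'   `n_fine`, `n_coarse`.
#' @export
label_hierarchy <- function(fine_to_coarse, fine_names = NULL, coarse_names = NULL) {
  fine_to_coarse <- as.integer(fine_to_coarse)
  if (anyNA(fine_to_coarse)) stop("every fine label needs a coarse parent")
  n_coarse <- max(fine_to_coarse) + 1L
  if (!all((seq_len(n_coarse) - 1L) %in% fine_to_coarse))
    warning("some coarse labels have no children")
  structure(list(fine_to_coarse = fine_to_coarse,
                 n_fine = length(fine_to_coarse), n_coarse = n_coarse,
                 fine_names = fine_names, coarse_names = coarse_names),
            class = "label_hierarchy")
}
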