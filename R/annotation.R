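#' Transfer labels to unlabeled cells by k-nearest neighbors
#'
#' Each unlabeled cell receives the majority label among its `k` nearest
#' labeled cells (Euclidean distance in the embedding).  Ties in the majority
#' vote are broken by the smaller mean distance to the tied labels'
#' neighbors, then by label id.
#'
#' @param embedding `n x d` matrix (e.g. from [encode()]).
#' @param labels Integer labels with `NA` for cells to annotate.
#' @param k Number of neighbors (default 10).
#' @return Integer vector of labels for all cells (observed labels kept).
#' @export
knn_transfer <- function(embedding, labels, k = 10L) {
  labeled <- which(!is.na(labels))
  if (length(labeled) < 1L) stop("need at least one labeled cell")
  if (k > length(labeled))
    stop("k = ", k, " exceeds the number of labeled cells (", length(labeled), ")")
  query <- which(is.na(labels))
  out <- labels
  if (!length(query)) return(out)
  ref <- embedding[labeled, , drop = FALSE]
  reflab <- labels[labeled]
  ref_sq <- rowSums(ref^2)
  qm <- embedding[query, , drop = FALSE]
  d2 <- outer(rowSums(qm^2), ref_sq, "+") - 2 * tcrossprod(qm, ref)
  for (i in seq_along(query)) {
    ord <- order(d2[i, ], seq_along(reflab))[seq_len(k)]
    nl <- reflab[ord]
    tab <- table(nl)
    topc <- names(tab)[tab == max(tab)]
    if (length(topc) > 1L) {
      md <- vapply(topc, function(cc) mean(d2[i, ord[nl == as.integer(cc)]]),
                   numeric(1))
      topc <- topc[order(md, as.integer(topc))]
    }
    out[query[i]] <- as.integer(topc[1])
  }
  out
}

#' Score cells against signed marker-gene signatures
#'
#' Cells are depth-normalized, transformed by `x -> log(1 + 1e4 x)`, each
#' gene is z-scored across cells (population standard deviation; genes with
#' zero variance get z-score 0), and for each signature the gene z-scores
#' are multiplied by their sign (+1 positive / -1 negative markers) and
#' averaged.
#'
#' @param dataset A [gene_expression_dataset()].
#' @param signatures A list of [signature_def()] objects.
#' @return `n_cells x n_signatures` score matrix (class
#'   `signature_score_table`), columns named by signature label.
#' @export
signature_scores <- function(dataset, signatures) {
  if (inherits(signatures, "signature_def")) signatures <- list(signatures)
  genes_needed <- unique(unlist(lapply(signatures, function(s) c(s$positive, s$negative))))
  missing <- setdiff(genes_needed, dataset$gene_ids)
  if (length(missing))
    stop("signature genes absent from dataset: ", paste(missing, collapse = ", "))
  X <- dataset$counts
  tot <- pmax(rowSums(X), 1)
  Xn <- log1p(1e4 * (X / tot))
  mu <- colMeans(Xn)
  sdv <- sqrt(colMeans(sweep(Xn, 2, mu)^2))   # population sd
  Z <- sweep(sweep(Xn, 2, mu), 2, ifelse(sdv > 0, sdv, 1), "/")
  Z[, sdv == 0] <- 0
  scores <- vapply(signatures, function(sg) {
    ip <- match(sg$positive, dataset$gene_ids)
    im <- match(sg$negative, dataset$gene_ids)
    sgn <- c(rep(1, length(ip)), rep(-1, length(im)))
    idx <- c(ip, im)
    as.vector(Z[, idx, drop = FALSE] %*% sgn) / length(idx)
  }, numeric(nrow(X)))
  colnames(scores) <- vapply(signatures, function(s) s$label, character(1))
  class(scores) <- c("signature_score_table", class(scores))
  scores
}

#' Select seed cells from signature scores
#'
#' For each signature the `top_n` highest-scoring cells become seed cells for
#' that label.  A cell reaching the top set of several labels is assigned to
#' the label where its rank (1 = best) is better; an exact rank tie leaves
#' the cell unassigned.
#'
#' @param scores Score matrix from [signature_scores()].
#' @param top_n Seeds per label (default 50).
#' @return Integer vector of label ids (0-based, column order of `scores`)
#'   with `NA` for non-seed cells.
#' @export
pick_seed_cells <- function(scores, top_n = 50L) {
  n <- nrow(scores); L <- ncol(scores)
  if (top_n > n) stop("top_n exceeds the number of cells")
  rank_in <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    ord <- order(-scores[, j], seq_len(n))
    rank_in[cbind(ord[seq_len(top_n)], j)] <- seq_len(top_n)
  }
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    rk <- rank_in[i, ]
    if (all(is.na(rk))) next
    best <- min(rk, na.rm = TRUE)
    cand <- which(rk == best)
    if (length(cand) == 1L) out[i] <- cand - 1L
  }
  out
}

#' Hierarchical label posterior
#'
#' For a semisupervised model trained with fine labels tied to a two-level
#' hierarchy, returns the classifier posterior at both levels: the fine-level
#' simplex from `q(c|z)` and the coarse-level simplex obtained by summing
#' each coarse label's children.
#'
#' @param model A fitted semisupervised [scvae()] model with a hierarchy.
#' @param dataset A [gene_expression_dataset()] over the model's genes.
#' @param constrain_observed_coarse When `TRUE` (default), a cell whose
#'   coarse label is observed in the dataset has its fine posterior
#'   restricted (renormalized) to that coarse label's subtree, so no fine
#'   mass falls outside the observed branch.
#' @return List of class `hierarchical_posterior` with elements `fine`
#'   (n x n_fine_total), `coarse` (n x n_coarse_total), `fine_labels`,
#'   `coarse_labels` (argmax predictions, 0-based).
#' @export
hierarchical_classify <- function(model, dataset,
                                  constrain_observed_coarse = TRUE) {
  if (is.null(model$hierarchy))
    stop("model was not trained with a label hierarchy")
  probs <- classify(model, dataset)
  hier <- model$hierarchy
  if (constrain_observed_coarse && !is.null(dataset$labels_coarse)) {
    for (i in which(!is.na(dataset$labels_coarse) & is.na(dataset$labels))) {
      kids <- which(hier$fine_to_coarse == dataset$labels_coarse[i])
      keep <- probs[i, kids]
      probs[i, ] <- 0
      probs[i, kids] <- keep / sum(keep)
    }
  }
  nc <- hier$n_coarse
  coarse <- matrix(0, nrow(probs), nc)
  for (cc in seq_len(nc) - 1L) {
    kids <- which(hier$fine_to_coarse == cc)
    coarse[, cc + 1L] <- rowSums(probs[, kids, drop = FALSE])
  }
  structure(list(fine = probs, coarse = coarse,
                 fine_labels = max.col(probs) - 1L,
                 coarse_labels = max.col(coarse) - 1L,
                 hierarchy = hier),
            class = "hierarchical_posterior")
}

#' @export
print.hierarchical_posterior <- function(x, ...) {
  cat(sprintf("hierarchical posterior: %d cells, %d fine / %d coarse classes\n",
              nrow(x$fine), ncol(x$fine), ncol(x$coarse)))
  invisible(x)
}
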