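# Evaluation statistics for harmonization and annotation.

euclid_knn <- function(emb, k, exclude_self = TRUE) {
  n <- nrow(emb)
  d2 <- outer(rowSums(emb^2), rowSums(emb^2), "+") - 2 * tcrossprod(emb)
  if (exclude_self) diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

#' Entropy of batch mixing
#'
#' Draws `T` query cells uniformly (with replacement); for each, forms the
#' batch-composition frequencies over its `n_neighbors` nearest cells
#' (Euclidean, self excluded) and computes the natural-log entropy
#' (`0 log 0 = 0`).  The mean over queries is returned: 0 for fully
#' separated batches, up to `log(K)` for perfectly mixed ones — higher
#' indicates stronger mixing.
#'
#' @param embedding `n x d` cell embedding.
#' @param batch_index Per-cell batch ids (at least two distinct batches).
#' @param n_neighbors Neighborhood size (default 50).
#' @param T Number of sampled query cells (default 100); `T = n` with
#'   `sample_queries = FALSE` uses every cell once.
#' @param seed RNG seed for the query draw.
#' @param sample_queries Sample queries with replacement (default) or use
#'   the first `T` cells deterministically when `FALSE` with `T = n`.
#' @return Mean neighborhood entropy (class `metric_report` attributes
#'   record the settings).
#' @export
entropy_of_batch_mixing <- function(embedding, batch_index, n_neighbors = 50L,
                                    T = 100L, seed = 1L,
                                    sample_queries = TRUE) {
  n <- nrow(embedding)
  batches <- sort(unique(batch_index))
  if (length(batches) < 2L) stop("entropy of batch mixing needs >= 2 batches")
  if (n_neighbors >= n) stop("n_neighbors must be smaller than the number of cells")
  if (sample_queries) {
    set.seed(seed)
    queries <- sample.int(n, T, replace = TRUE)
  } else {
    queries <- rep_len(seq_len(n), T)
  }
  nn <- euclid_knn(embedding, n_neighbors)
  ent <- vapply(queries, function(i) {
    f <- tabulate(match(batch_index[nn[i, ]], batches), length(batches)) / n_neighbors
    f <- f[f > 0]
    -sum(f * log(f))
  }, numeric(1))
  metric_report(mean(ent), "entropy_of_batch_mixing",
                settings = list(n_neighbors = n_neighbors, T = T, seed = seed))
}

#' k-nearest-neighbor purity of a joint embedding
#'
#' For each batch, the k-NN sets of its cells are built twice: in a
#' batch-only embedding and in the joint embedding restricted to that
#' batch's cells.  The per-cell intersection-over-union of the two neighbor
#' sets is averaged over cells, and the batch means are averaged.  1 means
#' the joint embedding preserves each dataset's internal structure exactly.
#'
#' @param joint_embedding `n x d` embedding of all cells.
#' @param individual_embeddings List of per-batch embeddings (one matrix per
#'   batch, rows matching that batch's cells in order).
#' @param batch_index Per-cell batch ids aligned with `joint_embedding`.
#' @param k Neighborhood size.
#' @return Mean purity in `[0, 1]` as a `metric_report`.
#' @export
knn_purity <- function(joint_embedding, individual_embeddings, batch_index, k = 10L) {
  batches <- sort(unique(batch_index))
  stopifnot(length(individual_embeddings) == length(batches))
  per_batch <- vapply(seq_along(batches), function(bi) {
    cells <- which(batch_index == batches[bi])
    ind <- individual_embeddings[[bi]]
    if (nrow(ind) != length(cells))
      stop("individual embedding ", bi, " does not cover its batch's cells")
    if (k >= length(cells)) stop("k must be smaller than the batch size")
    nn_ind <- euclid_knn(ind, k)
    nn_joint <- euclid_knn(joint_embedding[cells, , drop = FALSE], k)
    mean(vapply(seq_along(cells), function(i) {
      a <- nn_ind[i, ]; b <- nn_joint[i, ]
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1)))
  }, numeric(1))
  metric_report(mean(per_batch), "knn_purity",
                settings = list(k = k), per_stratum = per_batch)
}

#' Weighted and unweighted classification accuracy
#'
#' Unweighted accuracy is the overall fraction of correct predictions.
#' Weighted accuracy averages the per-class accuracies with equal class
#' weights, so rare cell types count as much as abundant ones; classes
#' absent from the truth are excluded.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return A `metric_report` scalar (the weighted accuracy) with attribute
#'   `unweighted` and per-class accuracies in `per_stratum`.
#' @export
weighted_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth have different lengths")
  keep <- !is.na(truth)
  predicted <- predicted[keep]; truth <- truth[keep]
  if (!length(truth)) stop("no ground-truth labels")
  classes <- sort(unique(truth))
  per_class <- vapply(classes, function(cc) mean(predicted[truth == cc] == cc),
                      numeric(1))
  out <- metric_report(mean(per_class), "weighted_accuracy",
                       per_stratum = stats::setNames(per_class, classes))
  attr(out, "unweighted") <- mean(predicted == truth)
  out
}

#' Adjusted Rand index between two partitions
#'
#' Standard permutation-model ARI computed from the contingency table.
#'
#' @param a,b Equal-length cluster assignment vectors.
#' @return Scalar ARI (1 = identical partitions, ~0 for independent ones).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions have different lengths")
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Structure preservation of an embedding under k-means
#'
#' Runs k-means (fixed seed, 10 restarts) on two embeddings of the same
#' cells and returns the adjusted Rand index between the two partitions: a
#' harmonization that preserves cluster structure scores near 1.
#'
#' @param embedding_before,embedding_after `n x d` matrices over the same
#'   cells.
#' @param n_clusters Number of k-means clusters (>= 2).
#' @param seed RNG seed for the k-means initializations.
#' @return ARI as a `metric_report`.
#' @export
kmeans_ari_preservation <- function(embedding_before, embedding_after,
                                    n_clusters, seed = 1L) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (n_clusters > nrow(embedding_before)) stop("n_clusters exceeds number of cells")
  set.seed(seed)
  ka <- stats::kmeans(embedding_before, centers = n_clusters, nstart = 10)
  kb <- stats::kmeans(embedding_after, centers = n_clusters, nstart = 10)
  metric_report(adjusted_rand_index(ka$cluster, kb$cluster),
                "kmeans_ari_preservation",
                settings = list(n_clusters = n_clusters, seed = seed))
}

#' Entropy of batch mixing within strata
#'
#' Computes [entropy_of_batch_mixing()] separately inside each stratum
#' (e.g. bins of a precomputed trajectory ordering), using all stratum cells
#' as query points.  Strata with fewer than `n_neighbors + 1` cells are
#' reported as `NA`.
#'
#' @param embedding,batch_index As in [entropy_of_batch_mixing()].
#' @param strata Per-cell bin ids covering all cells.
#' @param n_neighbors Neighborhood size.
#' @param seed RNG seed (recorded; queries are exhaustive per stratum).
#' @return Named vector of per-stratum entropies as a `metric_report`.
#' @export
stratified_mixing <- function(embedding, batch_index, strata,
                              n_neighbors = 50L, seed = 1L) {
  if (length(strata) != nrow(embedding)) stop("strata must cover all cells")
  bins <- sort(unique(strata))
  vals <- vapply(bins, function(b) {
    cells <- which(strata == b)
    if (length(cells) < n_neighbors + 1L) return(NA_real_)
    if (length(unique(batch_index[cells])) < 2L) return(0)
    as.numeric(entropy_of_batch_mixing(embedding[cells, , drop = FALSE],
                                       batch_index[cells],
                                       n_neighbors = n_neighbors,
                                       T = length(cells), seed = seed,
                                       sample_queries = FALSE))
  }, numeric(1))
  metric_report(stats::setNames(vals, bins), "stratified_mixing",
                settings = list(n_neighbors = n_neighbors, seed = seed))
}

#' Consistency between an RNA embedding and protein measurements
#'
#' `mse`: mean over cells of the squared distance between the cell's protein
#' vector and the average protein vector of its `k` nearest neighbors in RNA
#' space.  `neighbor_overlap`: mean intersection-over-union of k-NN sets
#' built in RNA space versus protein space.
#'
#' @param rna_embedding `n x d` embedding.
#' @param protein_matrix `n x p` protein measurements (rows aligned).
#' @param k Neighborhood size.
#' @return List with `mse` and `neighbor_overlap`.
#' @export
protein_consistency <- function(rna_embedding, protein_matrix, k = 10L) {
  n <- nrow(rna_embedding)
  if (nrow(protein_matrix) != n) stop("protein rows must align with embedding rows")
  if (k >= n) stop("k must be smaller than the number of cells")
  nn_rna <- euclid_knn(rna_embedding, k)
  nn_prot <- euclid_knn(as.matrix(protein_matrix), k)
  mse <- mean(vapply(seq_len(n), function(i) {
    avg <- colMeans(protein_matrix[nn_rna[i, ], , drop = FALSE])
    sum((protein_matrix[i, ] - avg)^2)
  }, numeric(1)))
  overlap <- mean(vapply(seq_len(n), function(i) {
    a <- nn_rna[i, ]; b <- nn_prot[i, ]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1)))
  list(mse = mse, neighbor_overlap = overlap)
}

metric_report <- function(value, name, settings = list(), per_stratum = NULL) {
  structure(value, metric = name, settings = settings,
            per_stratum = per_stratum, class = c("metric_report", class(value)))
}

#' @export
print.metric_report <- function(x, ...) {
  cat(attr(x, "metric"), ":", paste(signif(unclass(x), 4), collapse = " "), "\n")
  st <- attr(x, "settings")
  if (length(st))
    cat("  settings:", paste(names(st), unlist(st), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
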