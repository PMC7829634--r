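test_that("entropy of batch mixing hits its closed-form cases", {
  # fully separated batch clusters: every neighborhood is pure
  emb <- rbind(matrix(rnorm(60, 0, 0.3), 30), matrix(rnorm(60, 50, 0.3), 30))
  b <- rep(0:1, each = 30)
  expect_equal(as.numeric(entropy_of_batch_mixing(emb, b, n_neighbors = 10,
                                                  T = 60, seed = 1)), 0)
  # period-4 batch pattern on a circle: every +-5 window holds exactly
  # half of each batch
  ang <- 2 * pi * (0:39) / 40
  emb2 <- cbind(cos(ang), sin(ang))
  b2 <- rep(c(0L, 0L, 1L, 1L), 10)
  e <- entropy_of_batch_mixing(emb2, b2, n_neighbors = 10, T = 40, seed = 1,
                               sample_queries = FALSE)
  expect_equal(as.numeric(e), log(2), tolerance = 1e-10)
  expect_error(entropy_of_batch_mixing(emb2, rep(0, 40)), "2 batches")
  expect_error(entropy_of_batch_mixing(emb2, b2, n_neighbors = 40), "smaller")
})

test_that("entropy of batch mixing equals exhaustive brute force", {
  set.seed(12)
  emb <- matrix(rnorm(90), 30, 3)
  b <- sample(0:2, 30, replace = TRUE)
  got <- as.numeric(entropy_of_batch_mixing(emb, b, n_neighbors = 7, T = 30,
                                            seed = 1, sample_queries = FALSE))
  ent <- vapply(1:30, function(i) {
    d <- sqrt(colSums((t(emb) - emb[i, ])^2)); d[i] <- Inf
    nb <- order(d)[1:7]
    f <- table(factor(b[nb], levels = 0:2)) / 7
    f <- f[f > 0]
    -sum(f * log(f))
  }, numeric(1))
  expect_equal(got, mean(ent), tolerance = 1e-12)
  # bounded by log(#batches) and invariant to isometries
  expect_lte(got, log(3))
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  got_rot <- as.numeric(entropy_of_batch_mixing(emb %*% R + 2, b, n_neighbors = 7,
                                                T = 30, seed = 1,
                                                sample_queries = FALSE))
  expect_equal(got_rot, got, tolerance = 1e-9)
})

test_that("kNN purity is 1 for identical embeddings and small under permutation", {
  set.seed(13)
  n <- 200
  emb <- matrix(rnorm(n * 4), n, 4)
  b <- rep(0:1, each = n / 2)
  ind <- list(emb[b == 0, ], emb[b == 1, ])
  expect_equal(as.numeric(knn_purity(emb, ind, b, k = 10)), 1)
  permuted <- emb[sample(n), ]
  expect_lt(as.numeric(knn_purity(permuted, ind, b, k = 10)), 0.2)
  expect_error(knn_purity(emb, ind, b, k = 100), "smaller")
})

test_that("kNN purity matches hand-computed neighbor sets on a 10-point instance", {
  set.seed(14)
  joint <- matrix(rnorm(20), 10, 2)
  ind <- matrix(rnorm(20), 10, 2)
  b <- rep(0L, 10)
  k <- 3
  nnsets <- function(M) lapply(1:10, function(i) {
    d <- sqrt(colSums((t(M) - M[i, ])^2)); d[i] <- Inf; order(d)[1:k]
  })
  a <- nnsets(ind); bb <- nnsets(joint)
  want <- mean(mapply(function(u, v) length(intersect(u, v)) / length(union(u, v)),
                      a, bb))
  expect_equal(as.numeric(knn_purity(joint, list(ind), b, k = k)), want,
               tolerance = 1e-12)
})

test_that("weighted accuracy averages per-class accuracies", {
  expect_equal(as.numeric(weighted_accuracy(c(0, 1, 2), c(0, 1, 2))), 1)
  # constant predictor over balanced classes: 1/C
  truth <- rep(0:3, each = 5)
  expect_equal(as.numeric(weighted_accuracy(rep(0, 20), truth)), 1 / 4)
  # per-class accuracies 1.0, 0.5, 0.0 average to 0.5
  truth3 <- c(0, 0, 1, 1, 2, 2)
  pred3 <- c(0, 0, 1, 2, 0, 1)
  wa <- weighted_accuracy(pred3, truth3)
  expect_equal(as.numeric(wa), 0.5)
  expect_equal(attr(wa, "unweighted"), 0.5)
  expect_error(weighted_accuracy(1:3, 1:4), "lengths")
  # a uniformly random predictor approaches 1/C in expectation
  set.seed(15)
  vals <- replicate(200, as.numeric(weighted_accuracy(sample(0:4, 100, TRUE),
                                                      sample(0:4, 100, TRUE))))
  expect_equal(mean(vals), 1 / 5, tolerance = 0.05)
})

test_that("adjusted Rand index matches its closed forms and mclust", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 7, 7)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(7, 7, 5, 5)), 1)
  set.seed(16)
  a <- sample(1:4, 500, TRUE); b <- sample(1:4, 500, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)
  # cross-check the contingency formula against the established implementation
  for (i in 1:5) {
    x <- sample(1:3, 60, TRUE); y <- sample(1:5, 60, TRUE)
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
})

test_that("k-means structure preservation is 1 for identical embeddings", {
  set.seed(17)
  emb <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 8), 50))
  expect_equal(as.numeric(kmeans_ari_preservation(emb, emb, 2, seed = 3)), 1)
  expect_error(kmeans_ari_preservation(emb, emb, 1), ">= 2")
  expect_error(kmeans_ari_preservation(emb, emb, 101), "exceeds")
})

test_that("stratified mixing reduces to the global metric and flags thin strata", {
  set.seed(18)
  emb <- matrix(rnorm(120), 60, 2)
  b <- rep(0:1, 30)
  one <- stratified_mixing(emb, b, strata = rep(1, 60), n_neighbors = 10, seed = 1)
  glob <- entropy_of_batch_mixing(emb, b, n_neighbors = 10, T = 60, seed = 1,
                                  sample_queries = FALSE)
  expect_equal(as.numeric(one), as.numeric(glob), tolerance = 1e-12)
  # strata identical to batches are pure: all zeros
  sep <- stratified_mixing(emb, b, strata = b, n_neighbors = 10, seed = 1)
  expect_equal(as.numeric(sep), c(0, 0))
  # one mixed stratum, one pure stratum -> (log 2, 0) pattern
  ang2 <- 2 * pi * (0:39) / 40
  emb2 <- rbind(cbind(cos(ang2), sin(ang2)),
                cbind(100 + cos(ang2[1:20]), sin(ang2[1:20])))
  b2 <- c(rep(c(0L, 0L, 1L, 1L), 10), rep(0L, 20))
  st <- c(rep(1, 40), rep(2, 20))
  mix <- stratified_mixing(emb2, b2, st, n_neighbors = 10, seed = 1)
  expect_equal(as.numeric(mix), c(log(2), 0), tolerance = 1e-10)
  # a stratum smaller than n_neighbors + 1 is reported missing
  thin <- stratified_mixing(emb, b, strata = c(rep(1, 55), rep(2, 5)),
                            n_neighbors = 10, seed = 1)
  expect_true(is.na(as.numeric(thin)[2]))
})

test_that("protein consistency matches hand computation and the null scale", {
  # 5-cell worked instance
  emb <- matrix(c(0, 1, 2, 3, 4), 5, 1)
  prot <- matrix(c(1, 2, 3, 4, 5, 10, 20, 30, 40, 50), 5, 2)
  r <- protein_consistency(emb, prot, k = 2)
  nn <- list(c(2, 3), c(1, 3), c(2, 4), c(3, 5), c(4, 3))
  want <- mean(vapply(1:5, function(i)
    sum((prot[i, ] - colMeans(prot[nn[[i]], , drop = FALSE]))^2), numeric(1)))
  expect_equal(r$mse, want, tolerance = 1e-12)
  expect_equal(r$neighbor_overlap, 1)   # same ordering in both spaces

  # smooth field: protein = embedding coordinates gives near-zero mse
  set.seed(19)
  emb2 <- matrix(runif(400), 200, 2)
  r2 <- protein_consistency(emb2, emb2, k = 3)
  expect_lt(r2$mse, 0.01)
  # random protein values: mse concentrates near sigma^2 (1 + 1/k) per protein
  prot3 <- matrix(rnorm(200 * 4), 200, 4)
  r3 <- protein_consistency(emb2, prot3, k = 5)
  expect_equal(r3$mse, 4 * (1 + 1 / 5), tolerance = 0.35)
  expect_error(protein_consistency(emb2, prot3, k = 200), "smaller")
})
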