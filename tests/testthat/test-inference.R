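test_that("training improves the ELBO and is reproducible under a fixed seed", {
  fit <- fix_unsup()
  tl <- fit$training_log
  expect_lte(nrow(tl), fit$config$n_epochs)
  # smoothed ELBO is non-decreasing over the last half of training
  sm <- stats::filter(tl$elbo, rep(1 / 5, 5), sides = 1)
  half <- sm[!is.na(sm)]
  half <- half[(length(half) %/% 2):length(half)]
  expect_gt(utils::tail(half, 1), utils::head(half, 1) - 1)
  expect_true(all(is.finite(tl$elbo)))
  # warmup: KL weight 0 at epoch 0, 1 from warmup_epochs on
  expect_equal(tl$kl_weight[1], 0)
  expect_equal(tl$kl_weight[tl$epoch >= fit$config$warmup_epochs],
               rep(1, sum(tl$epoch >= fit$config$warmup_epochs)))

  ds <- fix_sim3()$dataset
  cfg <- vae_config(n_hidden = 16, n_layers = 1, d_latent = 4, n_epochs = 5,
                    warmup_epochs = 3, seed = 9)
  f1 <- scvae(ds, "unsupervised", cfg)
  f2 <- scvae(ds, "unsupervised", cfg)
  expect_identical(f1$training_log$elbo, f2$training_log$elbo)
  expect_identical(encode(f1, ds), encode(f2, ds))
})

test_that("unsupervised mode ignores labels entirely", {
  ds <- fix_sim3()$dataset
  cfg <- vae_config(n_hidden = 16, n_layers = 1, d_latent = 4, n_epochs = 4,
                    warmup_epochs = 2, seed = 5)
  f1 <- scvae(ds, "unsupervised", cfg)
  ds_perm <- ds
  set.seed(1); ds_perm$labels <- sample(ds$labels)
  f2 <- scvae(ds_perm, "unsupervised", cfg)
  expect_identical(encode(f1, ds), encode(f2, ds))
  expect_error(classify(f1, ds), "unsupervised")
})

test_that("the embedding has the configured shape and separates simulated types", {
  fit <- fix_unsup()
  ds <- fix_sim3()$dataset
  z <- encode(fit, ds)
  expect_equal(dim(z), c(ds$n_cells, fit$config$d_latent))
  set.seed(2)
  km <- stats::kmeans(z, 3, nstart = 10)
  expect_gte(adjusted_rand_index(km$cluster, ds$labels), 0.9)
  # gene mismatch is caught
  ds_bad <- subset_genes(ds, ds$gene_ids[1:10])
  expect_error(encode(fit, ds_bad), "missing model genes")
})

test_that("the label posterior is a calibrated simplex with unobserved classes", {
  fit <- fix_semi()
  sim <- fix_sim3()
  probs <- classify(fit, sim$dataset)
  expect_equal(ncol(probs), fit$n_labels)
  expect_equal(fit$n_labels, fit$n_labels_observed + 1)  # one unobserved class
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  mpp <- max_posterior_probability(probs)
  expect_true(all(mpp >= 0 & mpp <= 1))
  # held-out accuracy on the simulated types
  hide <- attr(fit, "hidden_cells")
  pred <- max.col(probs) - 1L
  wa <- weighted_accuracy(pred[hide], sim$truth$labels[hide])
  expect_gte(as.numeric(wa), 0.85)
})

test_that("harmonization mixes batches better than raw-count PCA", {
  fit <- fix_unsup()
  ds <- fix_sim3()$dataset
  z <- encode(fit, ds)
  pc <- stats::prcomp(ds$counts)$x[, 1:8]
  ebm_z <- entropy_of_batch_mixing(z, ds$batch, n_neighbors = 30, seed = 1)
  ebm_pc <- entropy_of_batch_mixing(pc, ds$batch, n_neighbors = 30, seed = 1)
  expect_gt(as.numeric(ebm_z), as.numeric(ebm_pc))
})

test_that("ELBO evaluation matches its structural identities", {
  G <- 3; C <- 3
  m <- tiny_model(G = G, C = C, mode = "semisupervised", seed = 2)
  x <- c(4, 0, 7)
  # zero out the classifier, u-encoder and z-prior networks: all label
  # components become identical and q(c|z) is uniform
  zero <- function(pp) { pp$W[] <- 0; pp$b[] <- 0; pp }
  m$par$enc_c$head <- zero(m$par$enc_c$head)
  m$par$enc_u$mu <- zero(m$par$enc_u$mu)
  m$par$enc_u$ls <- zero(m$par$enc_u$ls)
  m$par$prior_z$mu <- zero(m$par$prior_z$mu)
  m$par$prior_z$ls <- zero(m$par$prior_z$ls)
  L <- elbo_labeled(m, x, 0, 1, n_mc = 50, seed = 31)
  U <- elbo_unlabeled(m, x, 0, n_mc = 50, seed = 31)
  # identical components + uniform label posterior: U = L + log C exactly
  expect_equal(as.numeric(U), as.numeric(L) + log(C), tolerance = 1e-9)
  # determinism of the Monte-Carlo evaluation under a fixed seed
  expect_identical(as.numeric(elbo_labeled(m, x, 0, 1, n_mc = 1, seed = 8)),
                   as.numeric(elbo_labeled(m, x, 0, 1, n_mc = 1, seed = 8)))
  expect_error(elbo_labeled(m, x, 0, NA), "missing")
  expect_error(elbo_labeled(m, x, 0, 99), "out of range")
})

test_that("a point-mass label posterior collapses U onto the labeled bound", {
  G <- 2; C <- 2
  m <- tiny_model(G = G, C = C, mode = "semisupervised", seed = 3)
  zero <- function(pp) { pp$W[] <- 0; pp$b[] <- 0; pp }
  m$par$enc_u$mu <- zero(m$par$enc_u$mu); m$par$enc_u$ls <- zero(m$par$enc_u$ls)
  m$par$prior_z$mu <- zero(m$par$prior_z$mu); m$par$prior_z$ls <- zero(m$par$prior_z$ls)
  # force q(c|z) to a point mass on class 0
  m$par$enc_c$head$W[] <- 0
  m$par$enc_c$head$b <- c(40, -40)
  x <- c(5, 1)
  L <- elbo_labeled(m, x, 0, 0, n_mc = 40, seed = 21)
  U <- elbo_unlabeled(m, x, 0, n_mc = 40, seed = 21)
  expect_equal(as.numeric(U), as.numeric(L), tolerance = 1e-8)
})

test_that("fitting a single-gene intercept-only model approaches the exact log-evidence", {
  # with a near-degenerate library prior and hand-set parameters the ELBO
  # equals the ZINB log-pmf up to the tiny residual l-jitter
  G <- 1
  m <- tiny_model(G = G, C = 1, mode = "unsupervised", seed = 4,
                  lib_mu = log(8), lib_var = exp(2 * scvae:::LOGSCALE_MIN))
  zero <- function(pp) { pp$W[] <- 0; pp$b[] <- 0; pp }
  for (nm in c("mu", "ls")) {
    m$par$enc_z[[nm]] <- zero(m$par$enc_z[[nm]])
    m$par$enc_l[[nm]] <- zero(m$par$enc_l[[nm]])
  }
  m$par$enc_l$mu$b <- log(8)
  m$par$enc_l$ls$b <- scvae:::LOGSCALE_MIN   # matches the prior exactly
  # decoder independent of z: zero every weight, keep head biases
  zero_mlp <- function(mm) { for (i in seq_along(mm$layers)) {
    mm$layers[[i]]$lin$W[] <- 0 }; mm }
  m$par$dec$shared <- zero_mlp(m$par$dec$shared)
  m$par$dec$branch_w <- zero_mlp(m$par$dec$branch_w)
  m$par$dec$branch_h <- zero_mlp(m$par$dec$branch_h)
  m$par$dec$head_w$W[] <- 0; m$par$dec$head_h$W[] <- 0
  m$par$dec$head_h$b[] <- -2
  x <- 5
  el <- elbo_unlabeled(m, x, 0, n_mc = 400, seed = 12)
  direct <- zinb_log_prob(x, mu = 8, theta = 1, pi = plogis(-2))
  expect_equal(as.numeric(el), direct, tolerance = 0.02)
})

test_that("a non-finite objective aborts with a diagnostic", {
  expect_error(
    scvae:::train_step(tiny_model(G = 2)$par,
                       X = matrix(c(1e308, 2, 3, 4), 2, 2) * NA,
                       s = c(0L, 0L), lab = c(NA_integer_, NA_integer_),
                       allowed = list(1:2, 1:2),
                       cfg = tiny_model(G = 2)$config, kappa = 1,
                       mode = "semisupervised", C = 2,
                       lib_mu = 0, lib_var = 1, cw = 1),
    "non-finite|missing|NA")
})

test_that("inverse-dispersion is recovered from simulated counts", {
  # single batch, moderate size: ranking of fitted theta matches the truth
  spec <- simulation_spec(n_cells = 1500, n_genes = 50, n_batches = 1,
                          n_labels = 2, seed = 31)
  sim <- simulate_dataset(spec)
  cfg <- vae_config(n_hidden = 32, n_layers = 2, d_latent = 8,
                    n_epochs = 50, warmup_epochs = 25, seed = 2)
  fit <- scvae(sim$dataset, "unsupervised", cfg)
  rho <- cor(log(coef(fit)), log(sim$truth$params$theta), method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("semisupervised warm start can reuse an unsupervised fit", {
  ds <- fix_sim3()$dataset
  ds$labels[sample(ds$n_cells, ds$n_cells - 40)] <- NA
  cfg <- vae_config(n_hidden = 16, n_layers = 1, d_latent = 4, n_epochs = 4,
                    warmup_epochs = 2, seed = 5, pretrain_epochs = 2)
  base <- scvae(ds, "unsupervised", cfg)
  fit <- scvae(ds, "semisupervised", cfg, init = base)
  expect_s3_class(fit, "scvae")
  expect_error(scvae(subset_cells(ds, 1:50) |> (\(d) { d$labels <- NULL; d })(),
                     "semisupervised", cfg), "at least one labeled")
})
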