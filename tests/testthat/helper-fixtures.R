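# Shared fixtures and independent oracles.  Expensive fits are built once
# per test run and cached.

.fix <- new.env(parent = emptyenv())

fix_cached <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# A small 3-type, 2-batch simulation shared across test files.
fix_sim3 <- function() fix_cached("sim3", function() {
  simulate_dataset(simulation_spec(n_cells = 600, n_genes = 60, n_batches = 2,
                                   n_labels = 3, seed = 101))
})

fix_cfg_small <- function(n_epochs = 100, ...) {
  vae_config(n_hidden = 48, n_layers = 2, d_latent = 10, n_epochs = n_epochs,
             warmup_epochs = 40, minibatch_size = 128, seed = 1,
             pretrain_epochs = 50, ...)
}

fix_unsup <- function() fix_cached("unsup", function() {
  scvae(fix_sim3()$dataset, "unsupervised", fix_cfg_small())
})

fix_semi <- function() fix_cached("semi", function() {
  sim <- fix_sim3()
  ds <- sim$dataset
  set.seed(3)
  hide <- sample(ds$n_cells, round(0.85 * ds$n_cells))
  ds$labels[hide] <- NA
  m <- scvae(ds, "semisupervised", fix_cfg_small())
  attr(m, "hidden_cells") <- hide
  m
})

# Build an untrained model object directly from freshly initialized
# parameters: any variational distribution gives a valid lower bound, so
# these are the subjects of the evidence-bound checks.
tiny_model <- function(G = 2, C = 2, K = 1, mode = "semisupervised",
                       seed = 1, lib_mu = log(20), lib_var = 0.25,
                       use_batchnorm = TRUE) {
  cfg <- vae_config(n_hidden = 4, n_layers = 2, d_latent = 1, d_u = 1,
                    use_batchnorm = use_batchnorm, seed = seed)
  set.seed(seed)
  par <- scvae:::init_params(mode, G, K, C, cfg,
                             x_log_mean_total = lib_mu,
                             log_freq_init = rep(-log(G), G))
  structure(list(par = par, mode = mode, config = cfg,
                 gene_ids = paste0("g", seq_len(G)), n_batches = K,
                 lib_mu = rep(lib_mu, K), lib_var = rep(lib_var, K),
                 n_labels = C, n_labels_observed = C, label_names = NULL,
                 hierarchy = NULL, training_log = NULL,
                 classifier_weight = 0, n_cells_trained = 0L),
            class = "scvae")
}

# Independent ZINB density for oracles: explicit mixture with dnbinom.
oracle_zinb <- function(x, mu, theta, pi) {
  pi * (x == 0) + (1 - pi) * stats::dnbinom(x, size = theta, mu = mu)
}

# Quadrature log-evidence for a tiny model (d_z = d_u = 1): integrates the
# generative model over (u, z, l) on dense grids, summing over labels for
# the unlabeled evidence.  Independent of the ELBO code path.
quad_log_evidence <- function(model, x, s = 0L, c = NA,
                              nz = 121, nu = 81, nl = 81) {
  G <- length(model$gene_ids)
  C <- model$n_labels
  par <- model$par
  zg <- seq(-8, 8, length.out = nz)
  lm <- model$lib_mu[s + 1]; lv <- model$lib_var[s + 1]
  logl <- seq(lm - 7 * sqrt(lv), lm + 7 * sqrt(lv), length.out = nl)
  # p(x | z, l, s): decoded frequencies/dropout per z grid point
  fd <- scvae:::dec_fwd(par$dec, matrix(zg, ncol = 1),
                        scvae:::one_hot(rep(s, nz), model$n_batches),
                        train = FALSE, noise = model$config$noise)
  px_z <- numeric(nz)
  dl <- logl[2] - logl[1]
  lden <- stats::dnorm(logl, lm, sqrt(lv))
  for (i in seq_len(nz)) {
    ll <- vapply(exp(logl), function(l)
      sum(log(oracle_zinb(x, l * (fd$w[i, ] + 1e-10),
                          exp(scvae:::clamp(par$log_theta, -6, 10)), fd$pi[i, ]))),
      numeric(1))
    m <- max(ll)
    px_z[i] <- m + log(sum(exp(ll - m) * lden) * dl)
  }
  dz <- zg[2] - zg[1]
  if (model$mode == "unsupervised") {
    pz <- stats::dnorm(zg)
    m <- max(px_z)
    return(m + log(sum(exp(px_z - m) * pz) * dz))
  }
  ug <- seq(-6, 6, length.out = nu)
  du <- ug[2] - ug[1]
  uden <- stats::dnorm(ug)
  log_p_xc <- vapply(seq_len(C) - 1L, function(cc) {
    fp <- scvae:::enc_gauss_fwd(par$prior_z,
                                cbind(matrix(ug, ncol = 1),
                                      scvae:::one_hot(rep(cc, nu), C)),
                                train = FALSE)
    pz <- vapply(zg, function(z)
      sum(stats::dnorm(z, fp$mu, fp$sd) * uden) * du, numeric(1))
    m <- max(px_z)
    log(1 / C) + m + log(sum(exp(px_z - m) * pz) * dz)
  }, numeric(1))
  if (!is.na(c)) return(log_p_xc[c + 1])
  m <- max(log_p_xc)
  m + log(sum(exp(log_p_xc - m)))
}

# Brute-force k nearest labeled neighbors (loops, plain dist).
oracle_knn_labels <- function(emb, labels, k) {
  out <- labels
  lab_idx <- which(!is.na(labels))
  for (i in which(is.na(labels))) {
    d <- sqrt(colSums((t(emb[lab_idx, , drop = FALSE]) - emb[i, ])^2))
    nb <- lab_idx[order(d, seq_along(d))[seq_len(k)]]
    tab <- sort(table(labels[nb]), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    if (length(top) > 1) {
      md <- sapply(top, function(cc) {
        sel <- nb[labels[nb] == as.integer(cc)]
        mean(sqrt(colSums((t(emb[sel, , drop = FALSE]) - emb[i, ])^2))^2)
      })
      top <- top[order(md, as.integer(top))]
    }
    out[i] <- as.integer(top[1])
  }
  out
}
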