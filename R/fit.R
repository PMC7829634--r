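# Model fitting: amortized variational inference for the ZINB deep
# generative model.  The four variational factors are
#   q(z|x) q(c|z) q(l|x) q(u|c,z)
# and the training objective is the sum of a labeled-cell bound L, an
# unlabeled-cell bound U that marginalizes the label under q(c|z), and an
# auxiliary classifier cross-entropy on labeled cells.  All gradients are
# hand-derived and checked against finite differences in the tests.

# ---- parameter initialization ---------------------------------------------

init_params <- function(mode, G, K, C, cfg, x_log_mean_total = 0,
                        log_freq_init = NULL) {
  h <- cfg$n_hidden; d <- cfg$d_latent; du <- cfg$d_u
  nl <- cfg$n_layers; bn <- cfg$use_batchnorm
  par <- list(
    enc_z = list(trunk = nn_mlp_init(G, h, nl, bn),
                 mu = nn_linear_init(h, d, scale = 1e-2),
                 ls = nn_linear_init(h, d, scale = 1e-2)),
    enc_l = list(trunk = nn_mlp_init(G, h, 1L, bn),
                 mu = nn_linear_init(h, 1L, scale = 1e-2),
                 ls = nn_linear_init(h, 1L, scale = 1e-2)),
    dec = list(shared = nn_mlp_init(d + K, h, 1L, bn),
               branch_w = if (nl > 1) nn_mlp_init(h + K, h, nl - 1L, bn),
               branch_h = if (nl > 1) nn_mlp_init(h + K, h, nl - 1L, bn),
               head_w = nn_linear_init(h, G, scale = 1e-2),
               head_h = nn_linear_init(h, G, scale = 1e-2)),
    log_theta = numeric(G)
  )
  # warm starts: library encoder biased to the data's log total counts and
  # frequency head biased to the overall gene frequencies
  par$enc_l$mu$b[] <- x_log_mean_total
  par$enc_l$ls$b[] <- -1
  if (!is.null(log_freq_init)) par$dec$head_w$b[] <- log_freq_init
  if (mode == "semisupervised") {
    par$enc_c <- list(trunk = nn_mlp_init(d, h, nl, bn),
                      head = nn_linear_init(h, C, scale = 1e-2))
    par$enc_u <- list(trunk = nn_mlp_init(d + C, h, nl, bn),
                      mu = nn_linear_init(h, du, scale = 1e-2),
                      ls = nn_linear_init(h, du, scale = 1e-2))
    par$prior_z <- list(trunk = nn_mlp_init(du + C, h, nl, bn),
                        mu = nn_linear_init(h, d, scale = 1e-2),
                        ls = nn_linear_init(h, d, scale = 1e-2))
  }
  par
}

# ---- sub-network forward/backward helpers ---------------------------------

# Gaussian encoder head: trunk MLP -> (mean, clamped log-sd).
enc_gauss_fwd <- function(pp, X, train) {
  r <- nn_mlp_fwd(pp$trunk, X, train)
  mu <- nn_linear_fwd(pp$mu, r$H)
  lsraw <- nn_linear_fwd(pp$ls, r$H)
  ls <- clamp(lsraw, LOGSCALE_MIN, LOGSCALE_MAX)
  list(mu = mu, ls = ls, sd = exp(ls),
       mask = (lsraw > LOGSCALE_MIN) & (lsraw < LOGSCALE_MAX),
       H = r$H, trunk_cache = r$cache, p = r$p)
}

enc_gauss_bwd <- function(pp, fw, X, dmu, dls) {
  dls <- dls * fw$mask
  r1 <- nn_linear_bwd(pp$mu, fw$H, dmu)
  r2 <- nn_linear_bwd(pp$ls, fw$H, dls)
  rt <- nn_mlp_bwd(pp$trunk, fw$trunk_cache, r1$dX + r2$dX)
  list(grads = list(trunk = list(layers = rt$grads), mu = r1$grad, ls = r2$grad),
       dX = rt$dX)
}

dec_fwd <- function(dec, z, S, train, noise) {
  in1 <- cbind(z, S)
  r1 <- nn_mlp_fwd(dec$shared, in1, train)
  dec$shared <- r1$p
  if (!is.null(dec$branch_w)) {
    inb <- cbind(r1$H, S)
    rw <- nn_mlp_fwd(dec$branch_w, inb, train); dec$branch_w <- rw$p
    rh <- nn_mlp_fwd(dec$branch_h, inb, train); dec$branch_h <- rh$p
    hw <- rw$H; hh <- rh$H
  } else {
    rw <- rh <- NULL; hw <- hh <- r1$H
  }
  lw <- nn_linear_fwd(dec$head_w, hw)
  w <- softmax_rows(lw)
  lh <- nn_linear_fwd(dec$head_h, hh)
  pi <- if (noise == "zinb") clamp(stats::plogis(lh), 1e-8, 1 - 1e-8) else lh * 0
  list(w = w, pi = pi, hw = hw, hh = hh,
       c1 = r1$cache, cw = rw$cache, ch = rh$cache, in1 = in1,
       inb = if (!is.null(dec$branch_w)) cbind(r1$H, S), dec = dec)
}

dec_bwd <- function(dec, fw, dw, dlh, d_z, noise) {
  dlw <- softmax_bwd(fw$w, dw)
  rW <- nn_linear_bwd(dec$head_w, fw$hw, dlw)
  rH <- nn_linear_bwd(dec$head_h, fw$hh, dlh)
  g <- list(head_w = rW$grad, head_h = rH$grad)
  if (!is.null(dec$branch_w)) {
    bw <- nn_mlp_bwd(dec$branch_w, fw$cw, rW$dX)
    bh <- nn_mlp_bwd(dec$branch_h, fw$ch, rH$dX)
    g$branch_w <- list(layers = bw$grads)
    g$branch_h <- list(layers = bh$grads)
    h <- ncol(dec$shared$layers[[length(dec$shared$layers)]]$lin$W)
    dh1 <- bw$dX[, seq_len(h), drop = FALSE] + bh$dX[, seq_len(h), drop = FALSE]
  } else {
    dh1 <- rW$dX + rH$dX
  }
  r1 <- nn_mlp_bwd(dec$shared, fw$c1, dh1)
  g$shared <- list(layers = r1$grads)
  list(grads = g, dz = r1$dX[, seq_len(d_z), drop = FALSE])
}

# Labeled-bound branch for rows `rows` at fixed labels `cc`:
#   A = log N(z; f_z_mu(u,c), f_z_sigma(u,c)) - KL(q(u|c,z) || N(0,I)) + log p(c)
# with u reparameterized from q(u|c,z).  `wv` are per-row weights applied in
# the backward pass (already including the 1/B and warmup factors).
branch_fwd_bwd <- function(par, z_rows, cc, C, log_prior_c, wv, train,
                           want_grads = TRUE) {
  Ccat <- one_hot(cc, C)
  Xu <- cbind(z_rows, Ccat)
  fu <- enc_gauss_fwd(par$enc_u, Xu, train)
  eps_u <- matrix(stats::rnorm(length(fu$mu)), nrow(fu$mu))
  uu <- fu$mu + fu$sd * eps_u
  Xp <- cbind(uu, Ccat)
  fp <- enc_gauss_fwd(par$prior_z, Xp, train)
  dev <- (z_rows - fp$mu) / fp$sd
  logN <- rowSums(-0.5 * dev^2 - fp$ls) - 0.5 * ncol(z_rows) * log(2 * pi)
  KLu <- rowSums(0.5 * (fu$mu^2 + fu$sd^2 - 1) - fu$ls)
  A <- logN - KLu + log_prior_c
  if (!want_grads) return(list(A = A))
  # backward (wv recycles down columns: one weight per row)
  wv <- as.vector(wv)
  dpmu <- wv * (dev / fp$sd)
  dpls <- wv * (dev^2 - 1)
  rp <- enc_gauss_bwd(par$prior_z, fp, Xp, dpmu, dpls)
  du <- rp$dX[, seq_len(ncol(uu)), drop = FALSE]
  dumu <- du - wv * fu$mu
  duls <- du * fu$sd * eps_u - wv * (fu$sd^2 - 1)
  ru <- enc_gauss_bwd(par$enc_u, fu, Xu, dumu, duls)
  dz <- ru$dX[, seq_len(ncol(z_rows)), drop = FALSE] - wv * (dev / fp$sd)
  list(A = A, dz = dz,
       grads = list(enc_u = ru$grads, prior_z = rp$grads),
       enc_u_p = fu$p, prior_z_p = fp$p)
}

# ---- one training step -----------------------------------------------------

# Returns updated (batchnorm) parameters, the gradient of the minibatch
# objective (to be *ascended*), and logging components.  `allowed` is a list
# of candidate-label vectors (1-based) for cells without a fine label.
train_step <- function(par, X, s, lab, allowed, cfg, kappa, mode, C,
                       lib_mu, lib_var, cw, train = TRUE, want_grads = TRUE) {
  B <- nrow(X); G <- ncol(X); K <- length(lib_mu)
  d <- cfg$d_latent
  bs <- 1 / B
  S <- one_hot(s, K)
  Xl <- log1p(X)
  grads <- list()

  fz <- enc_gauss_fwd(par$enc_z, Xl, train); par$enc_z$trunk <- fz$p
  eps_z <- matrix(stats::rnorm(B * d), B, d)
  z <- fz$mu + fz$sd * eps_z
  fl <- enc_gauss_fwd(par$enc_l, Xl, train); par$enc_l$trunk <- fl$p
  eps_l <- matrix(stats::rnorm(B), B, 1)
  log_l <- fl$mu + fl$sd * eps_l
  l <- exp(log_l)

  fd <- dec_fwd(par$dec, z, S, train, cfg$noise); par$dec <- fd$dec
  w <- fd$w + 1e-10
  mu <- as.vector(l) * w
  theta_v <- if (cfg$noise == "poisson") rep(1e8, G) else exp(clamp(par$log_theta, -6, 10))
  Th <- matrix(theta_v, B, G, byrow = TRUE)
  lp <- zinb_log_prob_mat(X, mu, Th, fd$pi)
  recon <- rowSums(lp)

  pm <- lib_mu[s + 1L]; pv <- lib_var[s + 1L]
  KLl <- 0.5 * log(pv) - fl$ls + (fl$sd^2 + (fl$mu - pm)^2) / (2 * pv) - 0.5
  KLl <- as.vector(KLl)

  comp <- list()
  dz <- matrix(0, B, d)
  dlogits_c <- NULL
  if (mode == "unsupervised") {
    KLz <- rowSums(0.5 * (fz$mu^2 + fz$sd^2 - 1) - fz$ls)
    elbo <- recon - KLz - KLl
    objective <- mean(recon - kappa * (KLz + KLl))
    comp$kl_z <- mean(KLz)
  } else {
    # T_q = -log q(z|x) at the sampled z (constant in eps under reparam.)
    Tq <- rowSums(fz$ls + 0.5 * eps_z^2) + 0.5 * d * log(2 * pi)
    Avals <- numeric(B)
    CE <- 0
    fine_obs <- !is.na(lab)
    lab_rows <- which(fine_obs)
    un_rows <- which(!fine_obs)
    fc <- NULL
    # classifier on all rows (value needed for U weights and CE)
    fc_r <- nn_mlp_fwd(par$enc_c$trunk, z, train); par$enc_c$trunk <- fc_r$p
    logits <- nn_linear_fwd(par$enc_c$head, fc_r$H)
    Q <- softmax_rows(logits)
    dlogits_c <- matrix(0, B, C)
    log_prior_c <- -log(C)
    # Assemble all (cell, candidate-label) pairs into one stacked batch:
    # an observed label contributes one pair at full weight; an unlabeled
    # cell one pair per candidate label, weighted by the classifier
    # posterior restricted to its candidate set.  A single forward/backward
    # through q(u|c,z) and the z-prior network then covers every term.
    pr <- lab_rows
    pc <- lab[lab_rows]
    pw <- rep(kappa * bs, length(lab_rows))
    groups <- list()
    if (length(un_rows)) {
      sig <- vapply(allowed[un_rows], paste, character(1), collapse = ",")
      for (gsig in unique(sig)) {
        rows <- un_rows[sig == gsig]
        Aset <- allowed[[rows[1]]]           # 1-based candidate labels
        la <- logits[rows, Aset, drop = FALSE]
        la <- la - apply(la, 1, max)
        qe <- exp(la)
        qn <- qe / rowSums(qe)
        groups[[length(groups) + 1L]] <-
          list(rows = rows, Aset = Aset, qn = qn, offset = length(pr))
        for (j in seq_along(Aset)) {
          pr <- c(pr, rows)
          pc <- c(pc, rep(Aset[j] - 1L, length(rows)))
          pw <- c(pw, kappa * bs * qn[, j])
        }
      }
    }
    br <- branch_fwd_bwd(par, z[pr, , drop = FALSE], pc, C, log_prior_c,
                         pw, train, want_grads)
    if (want_grads) {
      grads$enc_u <- br$grads$enc_u
      grads$prior_z <- br$grads$prior_z
      par$enc_u$trunk <- br$enc_u_p
      par$prior_z$trunk <- br$prior_z_p
      agg <- rowsum(br$dz, pr)
      rid <- as.integer(rownames(agg))
      dz[rid, ] <- dz[rid, ] + agg
    }
    if (length(lab_rows)) {
      Avals[lab_rows] <- br$A[seq_along(lab_rows)]
      # auxiliary cross-entropy on labeled cells
      qlab <- Q[cbind(lab_rows, lab[lab_rows] + 1L)]
      CE <- CE + sum(log(pmax(qlab, 1e-12)))
      oh <- one_hot(lab[lab_rows], C)
      dlogits_c[lab_rows, ] <- dlogits_c[lab_rows, ] +
        cw * bs * (oh - Q[lab_rows, , drop = FALSE])
    }
    for (g in groups) {
      rows <- g$rows; Aset <- g$Aset; qn <- g$qn
      Amat <- matrix(br$A[g$offset + seq_len(length(rows) * length(Aset))],
                     length(rows), length(Aset))
      lqn <- log(pmax(qn, 1e-12))
      Avals[rows] <- rowSums(qn * Amat) - rowSums(qn * lqn)
      if (want_grads) {
        gq <- Amat - lqn - 1
        dlogits_c[rows, Aset] <- dlogits_c[rows, Aset] +
          kappa * bs * softmax_bwd(qn, gq)
      }
      # cross-entropy at the coarse level for subtree-constrained cells
      if (length(Aset) < C) {
        Ssub <- rowSums(Q[rows, Aset, drop = FALSE])
        CE <- CE + sum(log(pmax(Ssub, 1e-12)))
        if (want_grads) {
          ind <- matrix(0, length(rows), C); ind[, Aset] <- 1
          dlogits_c[rows, ] <- dlogits_c[rows, ] + cw * bs *
            (Q[rows, , drop = FALSE] * (ind / Ssub) -
               Q[rows, , drop = FALSE])
        }
      }
    }
    elbo <- recon + Avals + Tq - KLl
    objective <- mean(recon + kappa * (Avals + Tq - KLl)) + cw * bs * CE
    comp$ce <- CE / max(1, length(lab_rows))
    comp$tq <- mean(Tq)
  }
  comp$recon <- mean(recon); comp$kl_l <- mean(KLl)
  if (!is.finite(objective)) {
    bad <- names(which(!vapply(comp, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite training objective (offending term: ",
         paste(if (length(bad)) bad else "unknown", collapse = ", "), ")")
  }
  if (!want_grads)
    return(list(par = par, objective = objective, elbo_sum = sum(elbo),
                elbo = elbo, comp = comp))

  # ---- backward: reconstruction into decoder, theta, l and z ----
  zg <- zinb_grad_mat(X, mu, Th, fd$pi, cfg$noise)
  dmu <- bs * zg$mu
  dw <- dmu * as.vector(l)
  dl_vec <- rowSums(dmu * w)
  dlh <- if (cfg$noise == "zinb") bs * zg$pi * fd$pi * (1 - fd$pi) else
    matrix(0, B, G)
  rdec <- dec_bwd(par$dec, fd, dw, dlh, d, cfg$noise)
  grads$dec <- rdec$grads
  dz <- dz + rdec$dz
  if (cfg$noise != "poisson") {
    tmask <- (par$log_theta > -6) & (par$log_theta < 10)
    grads$log_theta <- bs * colSums(zg$theta) * theta_v * tmask
  }

  # classifier gradients flow into enc_c and onwards into z
  if (!is.null(dlogits_c)) {
    rh <- nn_linear_bwd(par$enc_c$head, fc_r$H, dlogits_c)
    rt <- nn_mlp_bwd(par$enc_c$trunk, fc_r$cache, rh$dX)
    grads$enc_c <- list(trunk = list(layers = rt$grads), head = rh$grad)
    dz <- dz + rt$dX
  }

  # l path: reconstruction + KL(q(l|x) || prior)
  dlogl <- dl_vec * as.vector(l)
  dlmu <- matrix(dlogl - kappa * bs * (as.vector(fl$mu) - pm) / pv, B, 1)
  dlls <- matrix(dlogl * as.vector(fl$sd) * as.vector(eps_l) -
                   kappa * bs * (as.vector(fl$sd)^2 / pv - 1), B, 1)
  rl <- enc_gauss_bwd(par$enc_l, fl, Xl, dlmu, dlls)
  grads$enc_l <- rl$grads

  # z path
  if (mode == "unsupervised") {
    dzmu <- dz - kappa * bs * fz$mu
    dzls <- dz * fz$sd * eps_z - kappa * bs * (fz$sd^2 - 1)
  } else {
    dzmu <- dz
    dzls <- dz * fz$sd * eps_z + kappa * bs   # + d T_q / d log-sd
  }
  rz <- enc_gauss_bwd(par$enc_z, fz, Xl, dzmu, dzls)
  grads$enc_z <- rz$grads

  list(par = par, grads = grads, objective = objective,
       elbo_sum = sum(elbo), elbo = elbo, comp = comp)
}

# matrix versions of the ZINB log-density and gradients (training hot path)
zinb_log_prob_mat <- function(X, mu, Th, Pi) {
  lt <- log(Th); ltm <- log(Th + mu)
  nb <- lgamma(X + Th) - lgamma(Th) - lgamma(X + 1) +
    Th * (lt - ltm) + X * (log(mu) - ltm)
  out <- log1p(-Pi) + nb
  z <- X == 0
  if (any(z)) {
    nb0 <- (Th * (lt - ltm))[z]
    a <- log(Pi[z]); b <- log1p(-Pi[z]) + nb0
    m <- pmax(a, b)
    out[z] <- ifelse(Pi[z] == 0, b, m + log(exp(a - m) + exp(b - m)))
  }
  out
}

zinb_grad_mat <- function(X, mu, Th, Pi, noise) {
  tm <- Th + mu
  lratio <- log(Th) - log(tm)
  dmu <- X / mu - (X + Th) / tm
  dth <- digamma(X + Th) - digamma(Th) + lratio + 1 - (X + Th) / tm
  dpi <- -1 / (1 - Pi)
  z <- X == 0
  if (any(z)) {
    nb0 <- exp(Th * lratio)
    denom <- Pi + (1 - Pi) * nb0
    wgt <- (1 - Pi) * nb0 / denom
    dmu[z] <- (wgt * (-Th / tm))[z]
    dth[z] <- (wgt * (lratio + mu / tm))[z]
    dpi[z] <- ((1 - nb0) / denom)[z]
  }
  list(mu = dmu, theta = dth, pi = dpi)
}

# ---- the fitting front end -------------------------------------------------

#' Fit the deep generative model to a dataset
#'
#' Trains a zero-inflated negative binomial variational autoencoder on a
#' multi-batch count dataset by stochastic optimization (Adam) of the
#' evidence lower bound.  In `"unsupervised"` mode the biological latent `z`
#' has a standard Gaussian prior and the model performs harmonization only.
#' In `"semisupervised"` mode `z` has a mixture prior indexed by the
#' (partially observed) cell-type label, the sum of a labeled and an
#' unlabeled bound is optimized together with an auxiliary classifier
#' cross-entropy, and the label posterior `q(c|z)` becomes a cell-type
#' classifier.  KL terms are annealed linearly over
#' `config$warmup_epochs` (deterministic warmup).
#'
#' @param dataset A [gene_expression_dataset()].  For semisupervised mode at
#'   least one cell must carry a label (fine or coarse).
#' @param mode `"unsupervised"` or `"semisupervised"`.
#' @param config A [vae_config()].
#' @param hierarchy Optional [label_hierarchy()] tying fine labels to coarse
#'   labels; cells labeled only at the coarse level constrain the label
#'   posterior to that subtree.
#' @param init Optional fitted `"unsupervised"` model to warm-start the
#'   encoder/decoder from (semisupervised mode); by default a short
#'   unsupervised pre-training run is performed internally
#'   (`config$pretrain_epochs`).
#' @param verbose Print per-epoch progress.
#' @return An object of class `scvae`; see [print.scvae()],
#'   [encode()], [classify()], [predict.scvae()], [simulate.scvae()].
#' @export
scvae <- function(dataset, mode = c("unsupervised", "semisupervised"),
                  config = vae_config(), hierarchy = NULL, init = NULL,
                  verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "gene_expression_dataset"))
  cfg <- config
  X <- dataset$counts
  n <- nrow(X); G <- ncol(X); K <- dataset$n_batches
  s <- dataset$batch

  # per-batch log-library priors estimated from the data
  logtot <- log(pmax(rowSums(X), 1))
  lib_mu <- vapply(0:(K - 1), function(k) mean(logtot[s == k]), numeric(1))
  lib_var <- vapply(0:(K - 1), function(k) {
    v <- stats::var(logtot[s == k]); if (!is.finite(v) || v < 1e-2) 1e-2 else v
  }, numeric(1))

  lab <- if (is.null(dataset$labels)) rep(NA_integer_, n) else dataset$labels
  coarse <- if (is.null(dataset$labels_coarse)) rep(NA_integer_, n) else dataset$labels_coarse
  C_obs <- if (!is.null(hierarchy)) hierarchy$n_fine else {
    if (all(is.na(lab))) 0L else max(lab, na.rm = TRUE) + 1L
  }
  C <- C_obs + cfg$n_unobserved
  hier_ext <- NULL
  if (!is.null(hierarchy)) {
    f2c <- c(hierarchy$fine_to_coarse,
             hierarchy$n_coarse + seq_len(cfg$n_unobserved) - 1L)
    hier_ext <- label_hierarchy(f2c, fine_names = hierarchy$fine_names,
                                coarse_names = hierarchy$coarse_names)
  }
  if (mode == "semisupervised") {
    if (all(is.na(lab)) && all(is.na(coarse)))
      stop("semisupervised mode needs at least one labeled cell")
    if (any(stats::na.omit(lab) >= C_obs))
      stop("label id exceeds the number of observed classes")
  }
  # candidate sets (1-based) for cells without a fine label
  allowed <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(lab[i])) next
    if (!is.na(coarse[i]) && !is.null(hierarchy)) {
      allowed[[i]] <- which(hierarchy$fine_to_coarse == coarse[i])
    } else allowed[[i]] <- seq_len(C)
  }
  frac_lab <- mean(!is.na(lab) | !is.na(coarse))
  cw <- if (is.null(cfg$classifier_weight)) 50 / max(frac_lab, 1e-3) else
    cfg$classifier_weight

  set.seed(cfg$seed)
  log_freq <- log(pmax(colSums(X), 0.5) / sum(pmax(colSums(X), 0.5)))
  par <- init_params(mode, G, K, C, cfg, x_log_mean_total = mean(logtot),
                     log_freq_init = log_freq)
  if (mode == "semisupervised") {
    pre_ep <- if (is.null(cfg$pretrain_epochs)) max(1L, cfg$n_epochs %/% 2L) else
      as.integer(cfg$pretrain_epochs)
    if (!is.null(init)) {
      stopifnot(inherits(init, "scvae"), init$mode == "unsupervised")
      for (nm in c("enc_z", "enc_l", "dec", "log_theta")) par[[nm]] <- init$par[[nm]]
    } else if (pre_ep > 0) {
      pre <- run_epochs(par, X, s, lab, allowed, cfg, "unsupervised", C,
                        lib_mu, lib_var, cw, pre_ep, verbose, tag = "pretrain")
      par <- pre$par
    }
  }
  run <- run_epochs(par, X, s, lab, allowed, cfg, mode, C, lib_mu, lib_var,
                    cw, cfg$n_epochs, verbose, tag = mode)
  structure(list(par = run$par, mode = mode, config = cfg,
                 gene_ids = dataset$gene_ids, n_batches = K,
                 lib_mu = lib_mu, lib_var = lib_var,
                 n_labels = C, n_labels_observed = C_obs,
                 label_names = dataset$label_names, hierarchy = hier_ext,
                 training_log = run$log, classifier_weight = cw,
                 n_cells_trained = n),
            class = "scvae")
}

run_epochs <- function(par, X, s, lab, allowed, cfg, mode, C, lib_mu, lib_var,
                       cw, n_epochs, verbose, tag = "") {
  n <- nrow(X)
  opt <- adam_init(par)
  logrows <- vector("list", n_epochs)
  best <- -Inf; stall <- 0L
  for (ep in seq_len(n_epochs) - 1L) {
    kappa <- if (cfg$warmup_epochs <= 0) 1 else min(1, ep / cfg$warmup_epochs)
    perm <- sample.int(n)
    elbo_tot <- 0
    for (start in seq(1L, n, by = cfg$minibatch_size)) {
      idx <- perm[start:min(start + cfg$minibatch_size - 1L, n)]
      if (length(idx) < 2L) next
      st <- train_step(par, X[idx, , drop = FALSE], s[idx], lab[idx],
                       allowed[idx], cfg, kappa, mode, C, lib_mu, lib_var, cw)
      par <- st$par
      upd <- adam_step(opt, par, nn_scale(st$grads, -1),
                       cfg$learning_rate, cfg$adam_eps)
      opt <- upd$opt; par <- upd$par
      elbo_tot <- elbo_tot + st$elbo_sum
    }
    elbo_ep <- elbo_tot / n
    logrows[[ep + 1L]] <- data.frame(epoch = ep, elbo = elbo_ep,
                                     kl_weight = kappa, phase = tag)
    if (verbose && (ep %% 25L == 0L))
      message(sprintf("[%s] epoch %d elbo %.2f kappa %.2f", tag, ep, elbo_ep, kappa))
    if (cfg$early_stop && kappa >= 1) {
      if (elbo_ep > best + 1e-4 * abs(best)) { best <- elbo_ep; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  list(par = par, log = do.call(rbind, logrows[!vapply(logrows, is.null, logical(1))]))
}
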