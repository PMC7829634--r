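# S3 methods and downstream accessors for fitted models.

check_genes <- function(model, dataset) {
  if (!identical(model$gene_ids, dataset$gene_ids)) {
    missing <- setdiff(model$gene_ids, dataset$gene_ids)
    if (length(missing))
      stop("dataset is missing model genes: ",
           paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) ", ...")
    stop("gene order differs from the training gene set; ",
         "use subset_genes(dataset, model$gene_ids)")
  }
  invisible(TRUE)
}

#' Embed cells in the harmonized latent space
#'
#' Returns the variational posterior mean of the biological latent `z` for
#' every cell: the batch-corrected embedding used for visualization,
#' clustering, label transfer and the harmonization metrics.
#'
#' @param model A fitted [scvae()] model.
#' @param dataset A [gene_expression_dataset()] over the training gene set.
#' @param chunk Number of cells processed per block.
#' @return `n_cells x d_latent` matrix of posterior means.
#' @export
encode <- function(model, dataset, chunk = 1024L) {
  check_genes(model, dataset)
  X <- dataset$counts
  out <- matrix(0, nrow(X), model$config$d_latent)
  for (start in seq(1L, nrow(X), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(X))
    fz <- enc_gauss_fwd(model$par$enc_z, log1p(X[idx, , drop = FALSE]), train = FALSE)
    out[idx, ] <- fz$mu
  }
  out
}

#' Posterior cell-type probabilities from the classifier head
#'
#' Evaluates `q(c | z)` at the posterior mean of `z` for every cell.  Columns
#' cover all modeled classes, including the reserved unobserved classes.
#'
#' @inheritParams encode
#' @return `n_cells x C` matrix of probabilities (rows sum to 1); attribute
#'   `n_observed` gives the number of observed classes (leading columns).
#' @export
classify <- function(model, dataset, chunk = 1024L) {
  if (model$mode != "semisupervised")
    stop("model was fit in unsupervised mode: no classifier available")
  z <- encode(model, dataset, chunk = chunk)
  probs <- classify_z(model, z)
  attr(probs, "n_observed") <- model$n_labels_observed
  probs
}

classify_z <- function(model, z) {
  r <- nn_mlp_fwd(model$par$enc_c$trunk, z, train = FALSE)
  probs <- softmax_rows(nn_linear_fwd(model$par$enc_c$head, r$H))
  cn <- paste0("class", seq_len(model$n_labels) - 1L)
  if (!is.null(model$label_names)) {
    k <- min(length(model$label_names), model$n_labels_observed)
    cn[seq_len(k)] <- model$label_names[seq_len(k)]
  }
  nun <- model$n_labels - model$n_labels_observed
  if (nun > 0)
    cn[model$n_labels_observed + seq_len(nun)] <- paste0("unobserved", seq_len(nun))
  colnames(probs) <- cn
  probs
}

#' Maximum posterior probability over the observed classes
#'
#' For each cell, the highest probability of being assigned to one of the
#' observed (annotated) classes; a low value flags cells the classifier can
#' only place in an unannotated population.
#'
#' @param probs Probability matrix from [classify()].
#' @param n_observed Number of observed classes (defaults to the attribute
#'   set by [classify()]).
#' @return Numeric vector of per-cell maxima.
#' @export
max_posterior_probability <- function(probs, n_observed = attr(probs, "n_observed")) {
  if (is.null(n_observed)) n_observed <- ncol(probs)
  apply(probs[, seq_len(n_observed), drop = FALSE], 1, max)
}

#' Extract generative parameters from a fitted model
#'
#' Wraps the fitted decoder networks, inverse-dispersions and library priors
#' as a [generative_parameters()] object, so the fitted model can be sampled
#' from with [sample_cells()] (used by [simulate.scvae()]).
#'
#' @param model A fitted [scvae()] model.
#' @return A [generative_parameters()] object.
#' @export
as_generative_parameters <- function(model) {
  par <- model$par
  cfg <- model$config
  K <- model$n_batches
  f_w <- function(z, s) {
    dec_fwd(par$dec, z, one_hot(s, K), train = FALSE, noise = cfg$noise)$w
  }
  f_h <- function(z, s) {
    if (cfg$noise != "zinb") return(matrix(0, nrow(z), length(model$gene_ids)))
    dec_fwd(par$dec, z, one_hot(s, K), train = FALSE, noise = cfg$noise)$pi
  }
  if (model$mode == "semisupervised") {
    C <- model$n_labels
    f_z_mu <- function(u, c) {
      fp <- enc_gauss_fwd(par$prior_z, cbind(u, one_hot(c, C)), train = FALSE)
      fp$mu
    }
    f_z_sigma <- function(u, c) {
      fp <- enc_gauss_fwd(par$prior_z, cbind(u, one_hot(c, C)), train = FALSE)
      fp$sd
    }
  } else {
    f_z_mu <- function(u, c) u
    f_z_sigma <- function(u, c) matrix(1, nrow(u), ncol(u))
  }
  generative_parameters(
    theta = exp(clamp(par$log_theta, -6, 10)),
    lib_mu = model$lib_mu, lib_var = model$lib_var,
    f_w = f_w, f_h = f_h, f_z_mu = f_z_mu, f_z_sigma = f_z_sigma,
    d_z = cfg$d_latent, d_u = cfg$d_u,
    n_labels = if (model$mode == "semisupervised") model$n_labels else 1L,
    noise = cfg$noise)
}

#' @export
print.scvae <- function(x, ...) {
  cat(sprintf("scvae model (%s): %d genes, %d batch(es), d_latent = %d\n",
              x$mode, length(x$gene_ids), x$n_batches, x$config$d_latent))
  if (x$mode == "semisupervised")
    cat(sprintf("  classes: %d observed + %d unobserved%s\n",
                x$n_labels_observed, x$n_labels - x$n_labels_observed,
                if (!is.null(x$hierarchy)) " (hierarchical)" else ""))
  if (!is.null(x$training_log) && nrow(x$training_log))
    cat(sprintf("  final training ELBO: %.2f (%d epochs)\n",
                utils::tail(x$training_log$elbo, 1),
                nrow(x$training_log)))
  invisible(x)
}

#' @export
summary.scvae <- function(object, ...) {
  th <- exp(clamp(object$par$log_theta, -6, 10))
  res <- list(mode = object$mode, n_genes = length(object$gene_ids),
              n_batches = object$n_batches,
              theta_quartiles = stats::quantile(th, c(0.25, 0.5, 0.75)),
              lib_mu = object$lib_mu, lib_var = object$lib_var,
              final_elbo = utils::tail(object$training_log$elbo, 1),
              n_epochs = nrow(object$training_log))
  class(res) <- "summary.scvae"
  res
}

#' @export
print.summary.scvae <- function(x, ...) {
  cat(sprintf("scvae (%s), %d genes, %d batches, final ELBO %.2f after %d epochs\n",
              x$mode, x$n_genes, x$n_batches, x$final_elbo, x$n_epochs))
  cat("inverse-dispersion quartiles:",
      paste(signif(x$theta_quartiles, 3), collapse = " / "), "\n")
  cat("log-library priors per batch: mu =",
      paste(signif(x$lib_mu, 3), collapse = ", "),
      " var =", paste(signif(x$lib_var, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.scvae <- function(object, ...) {
  stats::setNames(exp(clamp(object$par$log_theta, -6, 10)), object$gene_ids)
}

#' Model-based predictions for a dataset
#'
#' @param object A fitted [scvae()] model.
#' @param dataset A [gene_expression_dataset()] over the model's genes.
#' @param type `"latent"` (posterior mean of `z`), `"labels"` (argmax of the
#'   classifier posterior, semisupervised only), `"probs"` (the full label
#'   posterior), `"frequencies"` (decoded expected expression frequencies
#'   `f_w(z, s)`), or `"dropout"` (decoded dropout probabilities).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.scvae <- function(object, dataset, type = c("latent", "labels", "probs",
                                                    "frequencies", "dropout"), ...) {
  type <- match.arg(type)
  if (type == "latent") return(encode(object, dataset))
  if (type == "probs") return(classify(object, dataset))
  if (type == "labels") {
    probs <- classify(object, dataset)
    return(max.col(probs) - 1L)
  }
  z <- encode(object, dataset)
  fd <- dec_fwd(object$par$dec, z, one_hot(dataset$batch, object$n_batches),
                train = FALSE, noise = object$config$noise)
  out <- if (type == "frequencies") fd$w else fd$pi
  colnames(out) <- object$gene_ids
  out
}

#' Simulate counts from a fitted model
#'
#' Draws new cells from the fitted generative process (posterior-free
#' ancestral sampling), one batch at a time.
#'
#' @param object A fitted [scvae()] model.
#' @param nsim Number of cells to draw.
#' @param seed Optional RNG seed.
#' @param batch Batch id to simulate from.
#' @param labels Optional label ids (semisupervised models).
#' @param ... Unused.
#' @return A counts matrix with attribute `latents` (the generating states).
#' @export
simulate.scvae <- function(object, nsim = 1, seed = NULL, batch = 0L,
                           labels = NULL, ...) {
  gp <- as_generative_parameters(object)
  r <- sample_cells(gp, n = nsim, batch = batch, labels = labels, seed = seed)
  out <- r$counts
  colnames(out) <- object$gene_ids
  attr(out, "latents") <- r$latents
  out
}

#' Pearson residuals under the fitted count model
#'
#' For each entry, `(x - E[x]) / sd(x)` where moments are those of the
#' zero-inflated negative binomial at the posterior means of the latent
#' variables: `E[x] = (1 - pi) mu` and
#' `Var[x] = (1 - pi) mu (1 + mu (pi + 1/theta))`.
#'
#' @param object A fitted [scvae()] model.
#' @param dataset A [gene_expression_dataset()] over the model's genes.
#' @param ... Unused.
#' @return Matrix of Pearson residuals (cells x genes).
#' @export
residuals.scvae <- function(object, dataset, ...) {
  check_genes(object, dataset)
  X <- dataset$counts
  Xl <- log1p(X)
  fz <- enc_gauss_fwd(object$par$enc_z, Xl, train = FALSE)
  fl <- enc_gauss_fwd(object$par$enc_l, Xl, train = FALSE)
  l <- exp(as.vector(fl$mu) + as.vector(fl$sd)^2 / 2)
  fd <- dec_fwd(object$par$dec, fz$mu, one_hot(dataset$batch, object$n_batches),
                train = FALSE, noise = object$config$noise)
  mu <- l * (fd$w + 1e-10)
  th <- matrix(exp(clamp(object$par$log_theta, -6, 10)), nrow(X), ncol(X),
               byrow = TRUE)
  pi <- fd$pi
  ex <- (1 - pi) * mu
  vx <- (1 - pi) * mu * (1 + mu * (pi + 1 / th))
  res <- (X - ex) / sqrt(pmax(vx, 1e-12))
  colnames(res) <- object$gene_ids
  res
}

#' Plot the training ELBO trajectory
#'
#' @param x A fitted [scvae()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scvae <- function(x, ...) {
  tl <- x$training_log
  graphics::plot(tl$epoch, tl$elbo, type = "l", xlab = "epoch",
                 ylab = "training ELBO (per cell)", ...)
  invisible(x)
}
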