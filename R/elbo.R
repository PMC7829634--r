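# Monte-Carlo evaluation of the variational bounds for individual cells.
# These reuse the training-step forward pass in evaluation mode (batchnorm
# running statistics, no gradients) on a minibatch of n_mc replicas of the
# cell, so each row is one reparameterized draw.

elbo_eval <- function(model, x, s, c = NA_integer_, n_mc = 100L, seed = NULL) {
  stopifnot(length(x) == length(model$gene_ids))
  if (s < 0 || s >= model$n_batches) stop("unknown batch id ", s)
  if (!is.null(seed)) set.seed(seed)
  n_mc <- as.integer(n_mc)
  X <- matrix(rep(as.numeric(x), each = n_mc), n_mc, length(x))
  lab <- rep(as.integer(c), n_mc)
  allowed <- lapply(seq_len(n_mc), function(i)
    if (is.na(lab[i])) seq_len(model$n_labels))
  st <- train_step(model$par, X, rep(as.integer(s), n_mc), lab, allowed,
                   model$config, kappa = 1, mode = model$mode,
                   C = model$n_labels, lib_mu = model$lib_mu,
                   lib_var = model$lib_var, cw = 0,
                   train = FALSE, want_grads = FALSE)
  draws <- st$elbo
  out <- mean(draws)
  attr(out, "se") <- stats::sd(draws) / sqrt(n_mc)
  attr(out, "draws") <- draws
  out
}

#' Labeled-cell evidence lower bound
#'
#' Monte-Carlo estimate of the variational bound on `log p(x, c | s)` for a
#' cell with an observed label: the expected value under the variational
#' posterior of
#' `log p(x|z,l,s) + log p(z|u,c) + log p(u) + log p(c) + log p(l|s)
#'  - log q(z|x) - log q(l|x) - log q(u|c,z)`,
#' using reparameterized draws.  For an unsupervised model the label is
#' ignored and the bound is on `log p(x | s)` with the standard Gaussian
#' `z`-prior.
#'
#' @param model A fitted [scvae()] model.
#' @param x Count vector over the model's genes.
#' @param s Batch id.
#' @param c Observed label id (0-based).
#' @param n_mc Number of Monte-Carlo draws.
#' @param seed Optional RNG seed.
#' @return Scalar bound estimate with attributes `se` (Monte-Carlo standard
#'   error) and `draws` (the per-draw values).
#' @export
elbo_labeled <- function(model, x, s, c, n_mc = 100L, seed = NULL) {
  if (model$mode == "semisupervised") {
    if (is.na(c)) stop("label is missing: use elbo_unlabeled()")
    if (c < 0 || c >= model$n_labels) stop("label id out of range")
  }
  elbo_eval(model, x, s, c = if (model$mode == "semisupervised") c else NA,
            n_mc = n_mc, seed = seed)
}

#' Unlabeled-cell evidence lower bound
#'
#' Monte-Carlo estimate of the variational bound on `log p(x | s)` for a cell
#' without a label.  In semisupervised mode the label is marginalized under
#' the classifier posterior: the bound is
#' `sum_c q(c|z) L_c + H(q(c|z))` plus the label-independent terms, which
#' reduces to [elbo_labeled()] when `q(c|z)` is a point mass.
#'
#' @inheritParams elbo_labeled
#' @return Scalar bound estimate with attributes `se` and `draws`.
#' @export
elbo_unlabeled <- function(model, x, s, n_mc = 100L, seed = NULL) {
  elbo_eval(model, x, s, c = NA, n_mc = n_mc, seed = seed)
}
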