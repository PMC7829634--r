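#' Training configuration for the variational autoencoder
#'
#' Defaults follow the reference setting used throughout: two fully connected
#' hidden layers of 128 ReLU units per network, a 10-dimensional latent
#' space, Adam with learning rate 0.001 and epsilon 0.01, minibatches of 128
#' cells, deterministic warmup of the KL terms, and batch normalization.
#'
#' @param n_hidden Hidden units per fully connected layer.
#' @param n_layers Hidden layers per network.
#' @param d_latent Dimension of the biological latent `z`.
#' @param d_u Dimension of the within-type latent `u` (defaults to
#'   `d_latent`; used in semisupervised mode only).
#' @param learning_rate Adam step size.
#' @param adam_eps Adam epsilon.
#' @param warmup_epochs Epochs over which the KL weight rises linearly from 0
#'   to 1 (deterministic warmup).
#' @param classifier_weight Weight of the auxiliary cross-entropy term on
#'   labeled cells in semisupervised mode.  `NULL` (default) resolves at fit
#'   time to `50 / fraction of labeled cells`.
#' @param minibatch_size Cells per stochastic gradient step.
#' @param n_epochs Training epochs.
#' @param seed RNG seed controlling initialization, minibatching and
#'   reparameterization draws.
#' @param use_batchnorm Whether hidden layers use batch normalization.
#' @param noise Count noise model: `"zinb"` (default), `"nb"` or `"poisson"`.
#' @param n_unobserved Number of extra latent cell-type classes reserved for
#'   populations without annotations (semisupervised mode).
#' @param pretrain_epochs Epochs of unsupervised warm-start before
#'   semisupervised training (`NULL`: half of `n_epochs`); set 0 to disable.
#' @param early_stop Stop when the smoothed training ELBO plateaus.
#' @param patience Plateau length (epochs) for early stopping.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(n_hidden = 128L, n_layers = 2L, d_latent = 10L,
                       d_u = NULL, learning_rate = 0.001, adam_eps = 0.01,
                       warmup_epochs = 400L, classifier_weight = NULL,
                       minibatch_size = 128L, n_epochs = 400L, seed = 0L,
                       use_batchnorm = TRUE, noise = c("zinb", "nb", "poisson"),
                       n_unobserved = 1L, pretrain_epochs = NULL,
                       early_stop = FALSE, patience = 30L) {
  noise <- match.arg(noise)
  if (is.null(d_u)) d_u <- d_latent
  cfg <- list(n_hidden = as.integer(n_hidden), n_layers = as.integer(n_layers),
              d_latent = as.integer(d_latent), d_u = as.integer(d_u),
              learning_rate = learning_rate, adam_eps = adam_eps,
              warmup_epochs = as.integer(warmup_epochs),
              classifier_weight = classifier_weight,
              minibatch_size = as.integer(minibatch_size),
              n_epochs = as.integer(n_epochs), seed = as.integer(seed),
              use_batchnorm = isTRUE(use_batchnorm), noise = noise,
              n_unobserved = as.integer(n_unobserved),
              pretrain_epochs = pretrain_epochs,
              early_stop = isTRUE(early_stop), patience = as.integer(patience))
  stopifnot(cfg$n_hidden >= 1, cfg$n_layers >= 1, cfg$d_latent >= 1,
            cfg$learning_rate > 0, cfg$minibatch_size >= 2, cfg$n_epochs >= 1)
  class(cfg) <- "vae_config"
  cfg
}
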