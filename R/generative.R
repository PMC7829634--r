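#' Construct the parameters of the deep generative count model
#'
#' The model generates each cell independently: a cell type `c` from a
#' categorical prior, a within-type latent `u ~ N(0, I)`, a biological latent
#' `z ~ N(f_z_mu(u, c), f_z_sigma(u, c))`, a library scaling factor
#' `l ~ LogNormal(lib_mu[s], lib_var[s])` with batch-specific priors, and
#' finally counts whose collapsed conditional is zero-inflated negative
#' binomial with mean `l * f_w(z, s)`, gene-wise inverse-dispersion `theta`
#' and dropout probability `f_h(z, s)`.
#'
#' The four conditional maps are supplied as plain R functions so the same
#' container serves both hand-built simulation parameters and decoder
#' networks extracted from a fitted model.
#'
#' @param theta Positive per-gene inverse-dispersion vector (length G).
#' @param lib_mu,lib_var Per-batch mean and variance of `log(l)` (length K).
#' @param f_w Function `(z, s)` -> cells x genes matrix of expected
#'   frequencies; rows on the simplex.  `z` is a cells x d_z matrix, `s` an
#'   integer batch vector.
#' @param f_h Function `(z, s)` -> cells x genes dropout probabilities in (0,1).
#' @param f_z_mu,f_z_sigma Functions `(u, c)` -> cells x d_z mean / positive
#'   scale (standard deviation) of the conditional prior of `z`.
#' @param label_prior Probability vector over the C cell types (default
#'   uniform).
#' @param d_z,d_u Latent dimensions (default 10 each).
#' @param n_labels Number of cell types C.
#' @param noise One of `"zinb"`, `"nb"`, `"poisson"`; `"nb"` forces dropout
#'   to zero, `"poisson"` additionally takes the large-theta limit.
#' @return An object of class `generative_parameters`.
#' @export
generative_parameters <- function(theta, lib_mu, lib_var, f_w, f_h,
                                  f_z_mu = NULL, f_z_sigma = NULL,
                                  label_prior = NULL, d_z = 10L, d_u = 10L,
                                  n_labels = 1L, noise = c("zinb", "nb", "poisson")) {
  noise <- match.arg(noise)
  stopifnot(all(theta > 0), all(lib_var > 0), length(lib_mu) == length(lib_var))
  if (is.null(label_prior)) label_prior <- rep(1 / n_labels, n_labels)
  stopifnot(abs(sum(label_prior) - 1) < 1e-8)
  if (is.null(f_z_mu)) f_z_mu <- function(u, c) u
  if (is.null(f_z_sigma)) f_z_sigma <- function(u, c) matrix(1, nrow(u), ncol(u))
  structure(list(theta = theta, lib_mu = lib_mu, lib_var = lib_var,
                 f_w = f_w, f_h = f_h, f_z_mu = f_z_mu, f_z_sigma = f_z_sigma,
                 label_prior = label_prior, d_z = as.integer(d_z),
                 d_u = as.integer(d_u), n_labels = as.integer(n_labels),
                 n_genes = length(theta), n_batches = length(lib_mu),
                 noise = noise),
            class = "generative_parameters")
}

#' Sample cells from the generative model
#'
#' Runs the generative process forward for `n` cells of one batch and returns
#' the counts together with the latent states that produced them.
#'
#' @param params A [generative_parameters()] object.
#' @param n Number of cells.
#' @param batch Batch id in `0..(K-1)`.
#' @param labels Optional integer label ids; drawn from the label prior when
#'   omitted.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with `counts` (n x G integer matrix) and `latents` (list
#'   with `c`, `u`, `z`, `l` and the realized `freq` and `dropout` matrices).
#' @export
sample_cells <- function(params, n, batch = 0L, labels = NULL, seed = NULL) {
  stopifnot(n >= 1)
  if (batch < 0 || batch >= params$n_batches)
    stop("unknown batch id ", batch, " (model has ", params$n_batches, " batches)")
  if (!is.null(seed)) set.seed(seed)
  C <- params$n_labels
  if (is.null(labels)) {
    labels <- sample.int(C, n, replace = TRUE, prob = params$label_prior) - 1L
  } else {
    labels <- rep_len(as.integer(labels), n)
    if (any(labels < 0 | labels >= C)) stop("label id out of range")
  }
  u <- matrix(stats::rnorm(n * params$d_u), n, params$d_u)
  zmu <- params$f_z_mu(u, labels)
  zsd <- params$f_z_sigma(u, labels)
  z <- zmu + zsd * matrix(stats::rnorm(n * params$d_z), n, params$d_z)
  l <- exp(stats::rnorm(n, params$lib_mu[batch + 1L],
                        sqrt(params$lib_var[batch + 1L])))
  s <- rep(batch, n)
  w <- params$f_w(z, s)
  h <- params$f_h(z, s)
  mu <- l * w
  G <- params$n_genes
  x <- switch(params$noise,
    zinb = rzinb(n * G, mu = pmax(mu, 1e-12), theta = rep(params$theta, each = n), pi = h),
    nb = stats::rnbinom(n * G, size = rep(params$theta, each = n), mu = pmax(mu, 1e-12)),
    poisson = stats::rpois(n * G, lambda = pmax(mu, 1e-12)))
  counts <- matrix(as.numeric(x), n, G)
  list(counts = counts,
       latents = list(c = labels, u = u, z = z, l = l, freq = w, dropout = h))
}

#' Marginal log-density of the biological latent under the mixture prior
#'
#' Evaluates `log p(z) = log sum_c p(c) Int N(z; f_z_mu(u,c), f_z_sigma(u,c))
#' N(u; 0, I) du` by Monte Carlo over `u` (shared draws across components).
#'
#' @param z A d_z vector or cells x d_z matrix of latent positions.
#' @param params A [generative_parameters()] object.
#' @param n_mc Number of Monte Carlo draws of `u`.
#' @param seed Optional RNG seed.
#' @return Log-density vector, one entry per row of `z`.
#' @export
log_mixture_prior_z <- function(z, params, n_mc = 512L, seed = NULL) {
  if (is.null(dim(z))) z <- matrix(z, 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(z); d <- ncol(z)
  C <- params$n_labels
  U <- matrix(stats::rnorm(n_mc * params$d_u), n_mc, params$d_u)
  # log p(z_i) = logmeanexp over draws of logsumexp over c of
  #   log p(c) + log N(z_i; mu(u_m, c), sd(u_m, c))
  comp <- array(NA_real_, c(n, n_mc, C))
  for (ci in seq_len(C)) {
    cm <- rep(ci - 1L, n_mc)
    mu <- params$f_z_mu(U, cm)       # n_mc x d
    sd <- params$f_z_sigma(U, cm)
    for (i in seq_len(n)) {
      dev <- sweep(mu, 2, z[i, ], "-") / sd
      comp[i, , ci] <- -0.5 * rowSums(dev^2) - rowSums(log(sd)) -
        0.5 * d * log(2 * pi) + log(params$label_prior[ci])
    }
  }
  apply(comp, 1, function(M) {
    lse <- apply(M, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
    m <- max(lse)
    m + log(mean(exp(lse - m)))
  })
}
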