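#' Zero-inflated negative binomial log probability
#'
#' Log density of the count model obtained by collapsing the
#' Gamma-Poisson-Bernoulli hierarchy: with probability `pi` the count is
#' forced to zero (dropout), otherwise it is negative binomial with mean `mu`
#' and inverse-dispersion `theta`:
#' \deqn{NB(x; \mu, \theta) = \frac{\Gamma(x+\theta)}{\Gamma(\theta)\,x!}
#'   \left(\frac{\theta}{\theta+\mu}\right)^\theta
#'   \left(\frac{\mu}{\theta+\mu}\right)^x.}
#' Larger `theta` means less overdispersion; `pi = 0` recovers the plain
#' negative binomial.  All arguments recycle to a common length.
#'
#' @param x Non-negative integer counts.
#' @param mu Positive means.
#' @param theta Positive inverse-dispersions.
#' @param pi Dropout probabilities in `[0, 1)`.
#' @return Log densities, numerically stable for counts up to at least 1e6.
#' @export
zinb_log_prob <- function(x, mu, theta, pi = 0) {
  n <- max(length(x), length(mu), length(theta), length(pi))
  x <- rep_len(x, n); mu <- rep_len(mu, n)
  theta <- rep_len(theta, n); pi <- rep_len(pi, n)
  if (any(x < 0) || any(x != floor(x)))
    stop("x must be non-negative integers")
  if (any(mu <= 0) || any(theta <= 0)) stop("mu and theta must be positive")
  if (any(pi < 0) || any(pi >= 1)) stop("pi must lie in [0, 1)")
  lt <- log(theta)
  ltm <- log(theta + mu)
  nb <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (lt - ltm) + x * (log(mu) - ltm)
  out <- log1p(-pi) + nb
  z <- x == 0
  if (any(z)) {
    # log(pi + (1-pi) * NB(0)) via logsumexp for stability
    nb0 <- (theta * (lt - ltm))[z]
    a <- log(pi[z])
    b <- log1p(-pi[z]) + nb0
    m <- pmax(a, b)
    lp0 <- ifelse(pi[z] == 0, b, m + log(exp(a - m) + exp(b - m)))
    out[z] <- lp0
  }
  out
}

#' Draw zero-inflated negative binomial counts
#' @param n Number of draws.
#' @inheritParams zinb_log_prob
#' @return Integer vector of length `n`.
#' @export
rzinb <- function(n, mu, theta, pi = 0) {
  x <- stats::rnbinom(n, size = theta, mu = mu)
  drop <- stats::runif(n) < pi
  x[drop] <- 0L
  x
}

# Gradients of the ZINB log-density with respect to mu, theta and pi.
# Used by the training loop; returns a list of matrices/vectors shaped
# like the (recycled) inputs.
zinb_grad <- function(x, mu, theta, pi) {
  tm <- theta + mu
  lratio <- log(theta) - log(tm)
  # positive-count branch
  dmu <- x / mu - (x + theta) / tm
  dth <- digamma(x + theta) - digamma(theta) + lratio + 1 - (x + theta) / tm
  dpi <- -1 / (1 - pi)
  z <- x == 0
  if (any(z)) {
    nb0 <- exp(theta * lratio)          # NB(0; mu, theta)
    denom <- pi + (1 - pi) * nb0
    w <- (1 - pi) * nb0 / denom         # posterior weight of the NB branch at 0
    dmu[z] <- (w * (-theta / tm))[z]
    dth[z] <- (w * (lratio + mu / tm))[z]
    dpi[z] <- ((1 - nb0) / denom)[z]
  }
  list(mu = dmu, theta = dth, pi = dpi)
}
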