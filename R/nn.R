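# Minimal fully-connected neural network machinery with hand-written
# reverse-mode gradients.  Everything operates on row-major minibatches
# (rows = cells) so the heavy lifting is dense BLAS matrix products.
# Gradients are verified against finite differences in the test suite.

nn_linear_init <- function(d_in, d_out, scale = sqrt(2 / d_in)) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = scale), d_in, d_out),
       b = numeric(d_out))
}

nn_linear_fwd <- function(p, X) {
  sweep(X %*% p$W, 2, p$b, "+")
}

nn_linear_bwd <- function(p, X, dY) {
  list(grad = list(W = crossprod(X, dY), b = colSums(dY)),
       dX = tcrossprod(dY, p$W))
}

nn_bn_init <- function(d) {
  list(gamma = rep(1, d), beta = numeric(d),
       run_mean = numeric(d), run_var = rep(1, d))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Batch normalization.  In training mode uses minibatch statistics and
# returns updated running moments; in eval mode uses the running moments.
nn_bn_fwd <- function(p, X, train) {
  if (train && nrow(X) > 1) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2, invstd, "*")
    p$run_mean <- (1 - BN_MOMENTUM) * p$run_mean + BN_MOMENTUM * mu
    p$run_var <- (1 - BN_MOMENTUM) * p$run_var + BN_MOMENTUM * v
  } else {
    invstd <- 1 / sqrt(p$run_var + BN_EPS)
    xhat <- sweep(sweep(X, 2, p$run_mean), 2, invstd, "*")
  }
  Y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(Y = Y, cache = list(xhat = xhat, invstd = invstd, train = train),
       p = p)
}

nn_bn_bwd <- function(p, cache, dY) {
  xhat <- cache$xhat
  n <- nrow(dY)
  ggamma <- colSums(dY * xhat)
  gbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, p$gamma, "*")
  if (cache$train && n > 1) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dX <- sweep(dxhat, 2, s1 / n) - sweep(xhat, 2, s2 / n, "*")
    dX <- sweep(dX, 2, cache$invstd, "*")
  } else {
    dX <- sweep(dxhat, 2, cache$invstd, "*")
  }
  list(grad = list(gamma = ggamma, beta = gbeta), dX = dX)
}

# An MLP trunk: n_layers blocks of linear (+ optional batchnorm) + ReLU.
nn_mlp_init <- function(d_in, d_hidden, n_layers, use_bn) {
  layers <- vector("list", n_layers)
  din <- d_in
  for (i in seq_len(n_layers)) {
    layers[[i]] <- list(lin = nn_linear_init(din, d_hidden),
                        bn = if (use_bn) nn_bn_init(d_hidden))
    din <- d_hidden
  }
  list(layers = layers, use_bn = use_bn)
}

nn_mlp_fwd <- function(p, X, train = TRUE) {
  caches <- vector("list", length(p$layers))
  H <- X
  for (i in seq_along(p$layers)) {
    ly <- p$layers[[i]]
    pre <- nn_linear_fwd(ly$lin, H)
    bnc <- NULL
    if (!is.null(ly$bn)) {
      r <- nn_bn_fwd(ly$bn, pre, train)
      p$layers[[i]]$bn <- r$p
      bnc <- r$cache
      act_in <- r$Y
    } else act_in <- pre
    out <- pmax(act_in, 0)
    caches[[i]] <- list(X = H, bn = bnc, mask = act_in > 0)
    H <- out
  }
  list(H = H, cache = caches, p = p)
}

nn_mlp_bwd <- function(p, cache, dH) {
  grads <- vector("list", length(p$layers))
  for (i in rev(seq_along(p$layers))) {
    cc <- cache[[i]]
    d <- dH * cc$mask
    gbn <- NULL
    if (!is.null(p$layers[[i]]$bn)) {
      r <- nn_bn_bwd(p$layers[[i]]$bn, cc$bn, d)
      gbn <- r$grad
      d <- r$dX
    }
    r <- nn_linear_bwd(p$layers[[i]]$lin, cc$X, d)
    grads[[i]] <- list(lin = r$grad, bn = gbn)
    dH <- r$dX
  }
  list(grads = grads, dX = dH)
}

# --- generic nested-list parameter utilities -------------------------------
# Parameter containers are nested lists whose numeric leaves are the trained
# arrays; lists may be named (sub-networks) or unnamed (layer stacks).

nn_indices <- function(x) {
  nms <- names(x)
  if (is.null(nms)) seq_along(x) else nms
}

nn_is_leafable <- function(x) {
  !is.null(x) && !is.logical(x) && !is.character(x) && !is.function(x)
}

nn_zeros_like <- function(a) {
  if (is.numeric(a)) return(a * 0)
  out <- a
  for (nm in nn_indices(a)) {
    if (!nn_is_leafable(a[[nm]])) next
    out[[nm]] <- nn_zeros_like(a[[nm]])
  }
  out
}

# Adam optimizer over a nested parameter list.  Leaves without a matching
# gradient (e.g. batchnorm running moments) are left untouched.
adam_init <- function(par) {
  list(m = nn_zeros_like(par), v = nn_zeros_like(par), t = 0L)
}

adam_step <- function(opt, par, grad, lr, eps, beta1 = 0.9, beta2 = 0.999) {
  opt$t <- opt$t + 1L
  t <- opt$t
  step <- function(p, g, m, v) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, m = m, v = v))
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      p <- p - lr * mhat / (sqrt(vhat) + eps)
      return(list(p = p, m = m, v = v))
    }
    for (nm in nn_indices(p)) {
      if (!nn_is_leafable(p[[nm]])) next
      g_nm <- if (is.null(g)) NULL else g[[nm]]
      r <- step(p[[nm]], g_nm, m[[nm]], v[[nm]])
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  r <- step(par, grad, opt$m, opt$v)
  opt$m <- r$m; opt$v <- r$v
  list(opt = opt, par = r$p)
}

# Accumulate gradient structures (a + b), tolerating NULL leaves.
nn_acc <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (nm in nn_indices(a)) out[[nm]] <- nn_acc(a[[nm]], b[[nm]])
  out
}

# Scale every numeric leaf of a gradient structure.
nn_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(a * s)
  out <- a
  for (nm in nn_indices(a)) out[[nm]] <- nn_scale(a[[nm]], s)
  out
}

# Numerically stable row-wise softmax with its backward pass.
softmax_rows <- function(A) {
  A <- A - apply(A, 1, max)
  E <- exp(A)
  E / rowSums(E)
}

# dL/dA for Y = softmax(A) given G = dL/dY.
softmax_bwd <- function(Y, G) {
  Y * (G - rowSums(G * Y))
}

# Log-scale clamp used by all scale heads; gradients vanish where clamped.
LOGSCALE_MIN <- -4
LOGSCALE_MAX <- 4
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

one_hot <- function(idx, n) {
  M <- matrix(0, length(idx), n)
  M[cbind(seq_along(idx), idx + 1L)] <- 1
  M
}
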