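# Bayes-factor differential expression.  Two mutually exclusive hypotheses
# per gene g, H1: E_s f_w^g(z_a, s) > E_s f_w^g(z_b, s) versus its
# complement, are scored by the log-posterior-odds K = logit p(H1), with
# batches marginalized under their empirical frequencies.

#' Bayes factor from an estimated hypothesis probability
#'
#' `K = log(p / (1 - p))`.  Before the logit, `p` is clamped to
#' `[1/(S+1), S/(S+1)]` where `S` is the Monte-Carlo sample count, so `K`
#' stays finite (add-one rule).
#'
#' @param p_h1 Estimated probability of the first hypothesis.
#' @param n_samples Total Monte-Carlo draws behind the estimate (`Inf` for
#'   an exact probability).
#' @return The Bayes factor K; `|K| > 3` is conventionally read as strong
#'   evidence (posterior odds of about exp(3) = 20).
#' @export
bayes_factor_from_p <- function(p_h1, n_samples = Inf) {
  if (is.finite(n_samples))
    p_h1 <- pmin(pmax(p_h1, 1 / (n_samples + 1)), n_samples / (n_samples + 1))
  log(p_h1) - log1p(-p_h1)
}

de_table <- function(p_h1, n_samples, gene_ids, threshold, settings) {
  K <- bayes_factor_from_p(p_h1, n_samples)
  structure(data.frame(gene_id = gene_ids, p_h1 = p_h1, bayes_factor = K,
                       is_de = abs(K) > threshold, stringsAsFactors = FALSE),
            settings = settings, class = c("bayes_factor_table", "data.frame"))
}

#' @export
print.bayes_factor_table <- function(x, ...) {
  st <- attr(x, "settings")
  cat(sprintf("bayes_factor_table: %d genes, %d called DE at |K| > %g (%s scheme)\n",
              nrow(x), sum(x$is_de), st$threshold, st$scheme))
  NextMethod()
}

# Empirical batch frequencies over a set of cells.
batch_frequencies <- function(batch_index, n_batches) {
  tabulate(batch_index + 1L, n_batches) / length(batch_index)
}

# Shared Monte-Carlo core: draws z for the two sides, evaluates decoded
# frequencies under every batch, and averages the H1 indicator with the
# batch frequencies p(s).
de_compare_freq <- function(model, draw_za, draw_zb, n_rounds, p_s) {
  G <- length(model$gene_ids)
  acc <- numeric(G)
  K <- model$n_batches
  for (r in seq_len(n_rounds)) {
    za <- draw_za(); zb <- draw_zb()
    for (s in which(p_s > 0) - 1L) {
      sv <- rep(s, nrow(za))
      fa <- dec_fwd(model$par$dec, za, one_hot(sv, K), train = FALSE,
                    noise = model$config$noise)$w
      fb <- dec_fwd(model$par$dec, zb, one_hot(sv, K), train = FALSE,
                    noise = model$config$noise)$w
      acc <- acc + p_s[s + 1L] * colMeans(fa > fb)
    }
  }
  acc / n_rounds
}

#' Cell-pair Bayes-factor differential expression
#'
#' Samples `n_pairs` cell pairs (one cell from each group, uniform with
#' replacement), draws latent positions from each cell's variational
#' posterior `q(z|x)`, decodes expected frequencies under batches drawn with
#' the empirical batch frequencies `p(s)`, and estimates per gene the
#' probability that group A's frequency exceeds group B's; exact ties count
#' against H1.  Works with models of either mode.
#'
#' @param model A fitted [scvae()] model.
#' @param dataset The dataset the cells come from (model's gene set).
#' @param group_a,group_b Disjoint integer vectors of cell indices (1-based).
#' @param n_pairs Number of sampled cell pairs (default 100).
#' @param n_latent_samples Posterior draws per pair (default 10).
#' @param threshold Decision threshold on `|K|` (default 3).
#' @param p_s Optional batch-probability vector; defaults to the empirical
#'   frequencies over the union of both groups.
#' @param seed RNG seed.
#' @return A `bayes_factor_table` data frame (gene_id, p_h1, bayes_factor,
#'   is_de) with sampling settings attached.
#' @export
de_pairs <- function(model, dataset, group_a, group_b, n_pairs = 100L,
                     n_latent_samples = 10L, threshold = 3, p_s = NULL,
                     seed = 1L) {
  check_genes(model, dataset)
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  # canonical orientation so that reversing the groups mirrors the draws
  flip <- FALSE
  if (min(group_b) < min(group_a) ||
      (min(group_b) == min(group_a) && length(group_b) < length(group_a))) {
    tmp <- group_a; group_a <- group_b; group_b <- tmp; flip <- TRUE
  }
  if (is.null(p_s))
    p_s <- batch_frequencies(dataset$batch[c(group_a, group_b)], model$n_batches)
  p_s <- p_s / sum(p_s)
  set.seed(seed)
  Xl <- log1p(dataset$counts)
  fza <- enc_gauss_fwd(model$par$enc_z, Xl[group_a, , drop = FALSE], train = FALSE)
  fzb <- enc_gauss_fwd(model$par$enc_z, Xl[group_b, , drop = FALSE], train = FALSE)
  ia <- sample.int(length(group_a), n_pairs, replace = TRUE)
  ib <- sample.int(length(group_b), n_pairs, replace = TRUE)
  d <- ncol(fza$mu)
  draw <- function(fz, ii) function() {
    fz$mu[ii, , drop = FALSE] +
      fz$sd[ii, , drop = FALSE] * matrix(stats::rnorm(n_pairs * d), n_pairs, d)
  }
  p_h1 <- de_compare_freq(model, draw(fza, ia), draw(fzb, ib),
                          n_latent_samples, p_s)
  S <- n_pairs * n_latent_samples * sum(p_s > 0)
  if (flip) p_h1 <- 1 - p_h1
  de_table(p_h1, S, model$gene_ids, threshold,
           settings = list(scheme = "pairs", n_pairs = n_pairs,
                           n_latent_samples = n_latent_samples,
                           threshold = threshold, seed = seed, p_s = p_s))
}

#' Label-conditional Bayes-factor differential expression
#'
#' For a semisupervised model, compares two cell-type labels without fixing
#' specific cells: the within-type latent `u` is drawn either from the
#' aggregate posterior of `u` over the cells assigned to each label
#' (default) or from its `N(0, I)` prior, mapped through the label-conditional
#' prior of `z`, decoded under batches drawn with frequencies `p(s)`, and the
#' per-gene H1 probability estimated as in [de_pairs()].
#'
#' @param model A fitted semisupervised [scvae()] model.
#' @param dataset Dataset used to form the aggregate posterior (and default
#'   `p_s`).
#' @param label_a,label_b Label ids (0-based) in the model's label set.
#' @param n_samples Monte-Carlo draws per side (default 1000).
#' @param use_aggregate_posterior Draw `u` from the aggregate posterior of
#'   the label's assigned cells (default) instead of the prior.
#' @param threshold Decision threshold on `|K|`.
#' @param p_s Optional batch probabilities; defaults to empirical
#'   frequencies over cells assigned to either label.
#' @param seed RNG seed.
#' @return A `bayes_factor_table` data frame.
#' @export
de_labels <- function(model, dataset, label_a, label_b, n_samples = 1000L,
                      use_aggregate_posterior = TRUE, threshold = 3,
                      p_s = NULL, seed = 1L) {
  if (model$mode != "semisupervised")
    stop("label-conditional DE needs a semisupervised model")
  C <- model$n_labels
  if (label_a < 0 || label_a >= C || label_b < 0 || label_b >= C)
    stop("label id out of range")
  check_genes(model, dataset)
  flip <- FALSE
  if (label_b < label_a) { tmp <- label_a; label_a <- label_b; label_b <- tmp; flip <- TRUE }
  z <- encode(model, dataset)
  probs <- classify_z(model, z)
  assigned <- max.col(probs) - 1L
  cells_a <- which(assigned == label_a)
  cells_b <- which(assigned == label_b)
  if (use_aggregate_posterior && (!length(cells_a) || !length(cells_b)))
    stop("a label has no assigned cells; rerun with use_aggregate_posterior = FALSE")
  if (is.null(p_s)) {
    cells <- c(cells_a, cells_b)
    p_s <- if (length(cells)) batch_frequencies(dataset$batch[cells], model$n_batches)
           else rep(1 / model$n_batches, model$n_batches)
  }
  p_s <- p_s / sum(p_s)
  set.seed(seed)
  du <- model$config$d_u
  draw_u <- function(cells) {
    if (!use_aggregate_posterior) {
      function() matrix(stats::rnorm(n_samples * du), n_samples, du)
    } else {
      Xl <- log1p(dataset$counts[cells, , drop = FALSE])
      fz <- enc_gauss_fwd(model$par$enc_z, Xl, train = FALSE)
      # q(u | c, z) evaluated at the cells' posterior-mean z
      function() {
        ii <- sample.int(length(cells), n_samples, replace = TRUE)
        lab <- rep(if (identical(cells, cells_a)) label_a else label_b, n_samples)
        fu <- enc_gauss_fwd(model$par$enc_u,
                            cbind(fz$mu[ii, , drop = FALSE], one_hot(lab, C)),
                            train = FALSE)
        fu$mu + fu$sd * matrix(stats::rnorm(n_samples * du), n_samples, du)
      }
    }
  }
  ua <- draw_u(cells_a); ub <- draw_u(cells_b)
  draw_z <- function(udraw, lab) function() {
    u <- udraw()
    fp <- enc_gauss_fwd(model$par$prior_z, cbind(u, one_hot(rep(lab, n_samples), C)),
                        train = FALSE)
    fp$mu + fp$sd * matrix(stats::rnorm(n_samples * ncol(fp$mu)), n_samples, ncol(fp$mu))
  }
  p_h1 <- de_compare_freq(model, draw_z(ua, label_a), draw_z(ub, label_b),
                          n_rounds = 1L, p_s = p_s)
  S <- n_samples * sum(p_s > 0)
  if (flip) p_h1 <- 1 - p_h1
  de_table(p_h1, S, model$gene_ids, threshold,
           settings = list(scheme = "labels", n_samples = n_samples,
                           aggregate_posterior = use_aggregate_posterior,
                           threshold = threshold, seed = seed, p_s = p_s))
}

#' Rank agreement between Bayes factors and true log-fold changes
#'
#' Spearman and Kendall rank correlations (average ranks for ties) between
#' the inferred Bayes factors and a vector of true per-gene log-fold
#' changes.
#'
#' @param bf_table A `bayes_factor_table` from [de_pairs()] or [de_labels()],
#'   or a numeric vector of Bayes factors.
#' @param true_lfc Per-gene true log-fold changes, aligned with the table's
#'   genes.
#' @return List with `spearman` and `kendall`; `NA` when either input is
#'   constant.
#' @export
rank_agreement <- function(bf_table, true_lfc) {
  K <- if (is.data.frame(bf_table)) bf_table$bayes_factor else as.numeric(bf_table)
  if (length(K) != length(true_lfc)) stop("gene sets are not aligned")
  if (stats::sd(K) == 0 || stats::sd(true_lfc) == 0)
    return(list(spearman = NA_real_, kendall = NA_real_))
  list(spearman = stats::cor(K, true_lfc, method = "spearman"),
       kendall = stats::cor(K, true_lfc, method = "kendall"))
}
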