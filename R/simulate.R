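# Model-faithful synthetic data with known ground truth.  The generator
# reuses the package's own generative process: label centroids in latent
# space, a linear latent-to-logit map followed by the softmax frequency
# head, batch-specific log-library priors and dropout levels, and ZINB
# counts.  True per-gene log-fold changes between labels are therefore known
# exactly from the noiseless label profiles.

#' Specify a simulation
#'
#' The default shape is the desk-scale differential-expression benchmark:
#' 4,000 cells, 200 genes, 5 cell types with tree-structured expression
#' profiles, and 2 batches differing in sequencing depth and dropout.
#'
#' @param n_cells Total cells (split across batches by `batch_proportions`).
#' @param n_genes Genes.
#' @param n_batches Batches.
#' @param n_labels Cell types.
#' @param label_proportions Expected cell-type proportions (uniform default).
#' @param batch_proportions Cell allocation across batches (uniform default).
#' @param lib_mu,lib_var Per-batch mean/variance of log library scale; the
#'   defaults give the second batch roughly 3x the depth of the first.
#' @param dropout Per-batch baseline dropout probability of the
#'   zero-inflation component.
#' @param theta Per-gene inverse-dispersions; default drawn log-normally
#'   (meanlog 0.7, sdlog 0.8), spanning strong to mild overdispersion.
#' @param separation Distance between label centroids in latent space.
#' @param within_sd Within-type latent variability (scale of the `u` effect).
#' @param n_de_per_edge Genes perturbed on each edge of the label tree
#'   (default: a fifth of the genes, reflecting the marker-rich composition
#'   of a highly-variable-gene panel).
#' @param effect_range Range (natural-log units) of per-edge perturbation
#'   magnitudes.
#' @param baseline_sd Spread of baseline gene log-abundances.
#' @param hierarchy Optional [label_hierarchy()] over the labels; when
#'   supplied, coarse labels are attached to the simulated dataset.
#' @param trajectory If `TRUE`, cells interpolate continuously between the
#'   first two label centroids (requires `n_labels = 2`); labels are the
#'   nearest endpoint and the true position `t` is returned.
#' @param profiles Optional explicit `n_labels x n_genes` matrix of label
#'   log-abundance profiles overriding the tree construction.
#' @param noise Count noise model passed to the generator.
#' @param seed RNG seed fixing profiles and draws.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cells = 4000L, n_genes = 200L, n_batches = 2L,
                            n_labels = 5L, label_proportions = NULL,
                            batch_proportions = NULL,
                            lib_mu = NULL, lib_var = NULL, dropout = NULL,
                            theta = NULL, separation = 4, within_sd = 0.6,
                            n_de_per_edge = NULL, effect_range = c(1, 2.5),
                            baseline_sd = 1.2, hierarchy = NULL,
                            trajectory = FALSE, profiles = NULL,
                            noise = "zinb", seed = 1L) {
  if (is.null(label_proportions)) label_proportions <- rep(1 / n_labels, n_labels)
  if (is.null(batch_proportions)) batch_proportions <- rep(1 / n_batches, n_batches)
  if (is.null(lib_mu)) lib_mu <- log(4000) + log(3) * (seq_len(n_batches) - 1L)
  if (is.null(lib_var)) lib_var <- rep(0.09, n_batches)
  if (is.null(dropout)) dropout <- seq(0.25, 0.08, length.out = n_batches)
  if (is.null(n_de_per_edge)) n_de_per_edge <- max(2L, n_genes %/% 5L)
  stopifnot(abs(sum(label_proportions) - 1) < 1e-8,
            length(lib_mu) == n_batches, length(dropout) == n_batches)
  if (trajectory && n_labels != 2L)
    stop("trajectory mode interpolates between exactly 2 label endpoints")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_batches = as.integer(n_batches), n_labels = as.integer(n_labels),
                 label_proportions = label_proportions,
                 batch_proportions = batch_proportions,
                 lib_mu = lib_mu, lib_var = lib_var, dropout = dropout,
                 theta = theta, separation = separation, within_sd = within_sd,
                 n_de_per_edge = as.integer(n_de_per_edge),
                 effect_range = effect_range, baseline_sd = baseline_sd,
                 hierarchy = hierarchy, trajectory = isTRUE(trajectory),
                 profiles = profiles, noise = noise, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Tree-structured label profiles: labels are leaves of a balanced binary
# tree; every edge perturbs a random gene subset, so tree distance between
# two labels translates into expression distance.
make_tree_profiles <- function(L, G, n_de, effect_range, baseline_sd) {
  base <- stats::rnorm(G, 0, baseline_sd)
  prof <- matrix(rep(base, each = L), L, G)
  recurse <- function(labs) {
    if (length(labs) <= 1L) return(invisible(NULL))
    # first label splits off first, so label 0 is the most distinct type
    half <- floor(length(labs) / 2)
    for (side in list(labs[seq_len(half)], labs[-seq_len(half)])) {
      genes <- sample.int(G, n_de)
      eff <- stats::runif(n_de, effect_range[1], effect_range[2]) *
        sample(c(-1, 1), n_de, replace = TRUE)
      prof[side, genes] <<- prof[side, genes, drop = FALSE] +
        matrix(rep(eff, each = length(side)), length(side))
      recurse(side)
    }
  }
  recurse(seq_len(L))
  prof
}

# Build generative parameters from a spec (profiles fixed by the spec seed).
spec_to_params <- function(spec) {
  set.seed(spec$seed)
  L <- spec$n_labels; G <- spec$n_genes
  prof <- if (!is.null(spec$profiles)) spec$profiles else
    make_tree_profiles(L, G, spec$n_de_per_edge, spec$effect_range,
                       spec$baseline_sd)
  d_extra <- 3L
  d_z <- L + d_extra
  # latent-to-logit map: label dims carry the profiles, extra dims small
  # random loadings for within-type expression variability
  W <- rbind(prof / spec$separation,
             matrix(stats::rnorm(d_extra * G, 0, 0.15), d_extra, G))
  centroids <- cbind(diag(spec$separation, L), matrix(0, L, d_extra))
  gene_dropout_offset <- stats::rnorm(G, 0, 0.5)
  theta <- if (!is.null(spec$theta)) spec$theta else
    exp(stats::rnorm(G, 0.7, 0.8))
  f_w <- function(z, s) softmax_rows(z %*% W)
  f_h <- function(z, s) {
    logit <- stats::qlogis(pmin(pmax(spec$dropout[s + 1L], 1e-4), 1 - 1e-4))
    p <- stats::plogis(outer(logit, gene_dropout_offset, "+"))
    clamp(p, 1e-6, 1 - 1e-6)
  }
  f_z_mu <- function(u, c) spec$within_sd * u + centroids[c + 1L, , drop = FALSE]
  f_z_sigma <- function(u, c) matrix(0.1, nrow(u), ncol(u))
  params <- generative_parameters(theta = theta, lib_mu = spec$lib_mu,
                                  lib_var = spec$lib_var,
                                  f_w = f_w, f_h = f_h,
                                  f_z_mu = f_z_mu, f_z_sigma = f_z_sigma,
                                  label_prior = spec$label_proportions,
                                  d_z = d_z, d_u = d_z, n_labels = L,
                                  noise = spec$noise)
  freqs <- softmax_rows(prof)       # noiseless per-label expected frequencies
  list(params = params, profiles = prof, freqs = freqs, centroids = centroids)
}

#' Simulate a multi-batch dataset with known ground truth
#'
#' Draws counts from the generative process configured by a
#' [simulation_spec()] and returns them with everything a benchmark needs:
#' true labels, latent states, noiseless per-label frequency profiles and
#' the exact log2 fold-change table between all label pairs.
#'
#' @param spec A [simulation_spec()].
#' @return List with `dataset` (a [gene_expression_dataset()]),
#'   `truth` (list: `labels`, `latents` per batch, `profiles`, `freqs`,
#'   `lfc` — an `L x L x G` array with `lfc[a, b, g] =
#'   log2(freq[a, g] / freq[b, g])`, `params`, and `t` in trajectory mode).
#' @export
simulate_dataset <- function(spec) {
  sp <- spec_to_params(spec)
  params <- sp$params
  set.seed(spec$seed + 1L)
  nb <- round(spec$n_cells * spec$batch_proportions)
  nb[spec$n_batches] <- spec$n_cells - sum(nb[-spec$n_batches])
  counts <- NULL; batch <- integer(0); labels <- integer(0)
  lat <- list(); tvals <- numeric(0)
  for (k in seq_len(spec$n_batches) - 1L) {
    if (nb[k + 1L] == 0) next
    if (spec$trajectory) {
      tt <- stats::runif(nb[k + 1L])
      lab_k <- as.integer(tt > 0.5)
      # endpoints interpolated: override the centroid lookup via f_z_mu
      params_k <- params
      cents <- sp$centroids
      params_k$f_z_mu <- function(u, c)
        spec$within_sd * u + (1 - tt) %o% cents[1, ] + tt %o% cents[2, ]
      r <- sample_cells(params_k, nb[k + 1L], batch = k, labels = lab_k)
      tvals <- c(tvals, tt)
    } else {
      r <- sample_cells(params, nb[k + 1L], batch = k)
      lab_k <- r$latents$c
    }
    counts <- rbind(counts, r$counts)
    batch <- c(batch, rep(k, nb[k + 1L]))
    labels <- c(labels, lab_k)
    lat[[k + 1L]] <- r$latents
  }
  coarse <- if (!is.null(spec$hierarchy))
    spec$hierarchy$fine_to_coarse[labels + 1L]
  ds <- gene_expression_dataset(counts, batch = batch, labels = labels,
                                labels_coarse = coarse,
                                n_batches = spec$n_batches)
  L <- spec$n_labels; G <- spec$n_genes
  lfc <- array(0, c(L, L, G))
  for (a in seq_len(L)) for (b in seq_len(L))
    lfc[a, b, ] <- log2(sp$freqs[a, ] / sp$freqs[b, ])
  list(dataset = ds,
       truth = list(labels = labels, latents = lat, profiles = sp$profiles,
                    freqs = sp$freqs, lfc = lfc, params = params,
                    t = if (spec$trajectory) tvals))
}

#' Flip labels between two groups (mislabeling robustness protocol)
#'
#' Swaps the labels of exactly `round(flip_fraction * group size)` cells of
#' each of the two groups, chosen uniformly at random, emulating annotation
#' noise.  The flipped index sets are recorded as attributes so the
#' operation can be undone.
#'
#' @param dataset A labeled [gene_expression_dataset()].
#' @param flip_fraction Fraction in `[0, 0.5]` of each group to flip.
#' @param label_pair Integer vector of the two label ids to swap between.
#' @param seed RNG seed.
#' @return The dataset with flipped labels; attributes `flipped_a` and
#'   `flipped_b` hold the cell indices whose labels were exchanged.
#' @export
simulate_mislabeled <- function(dataset, flip_fraction, label_pair, seed = 1L) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 0.5, length(label_pair) == 2)
  lab <- dataset$labels
  if (is.null(lab)) stop("dataset has no labels")
  a <- which(lab == label_pair[1]); b <- which(lab == label_pair[2])
  if (!length(a) || !length(b)) stop("a label of the pair is absent")
  set.seed(seed)
  na <- round(flip_fraction * length(a)); nbn <- round(flip_fraction * length(b))
  fa <- if (na) sample(a, na) else integer(0)
  fb <- if (nbn) sample(b, nbn) else integer(0)
  lab[fa] <- label_pair[2]; lab[fb] <- label_pair[1]
  out <- dataset
  out$labels <- lab
  attr(out, "flipped_a") <- fa
  attr(out, "flipped_b") <- fb
  out
}

#' Simulate two datasets with controlled cell-type composition overlap
#'
#' Splits a two-batch simulation into two single-batch datasets whose label
#' compositions follow one of three scenarios: `"disjoint"` (the first
#' dataset holds only label 0, the second all other labels), `"one_unique"`
#' (label 0 removed from the second dataset only) and `"partial_overlap"`
#' (each dataset lacks one label present in the other, the rest shared).
#'
#' @param spec A [simulation_spec()] with `n_batches = 2` and
#'   `n_labels >= 2`.
#' @param mode Composition scenario.
#' @return List with the two datasets `a` and `b`, the unsplit simulation
#'   `full` (with its `truth`), and `kept` — the indices of `full` retained
#'   in each output.
#' @export
simulate_composition_scenario <- function(spec,
                                          mode = c("disjoint", "one_unique",
                                                   "partial_overlap")) {
  mode <- match.arg(mode)
  stopifnot(spec$n_batches == 2L, spec$n_labels >= 2L)
  sim <- simulate_dataset(spec)
  ds <- sim$dataset
  lab <- ds$labels
  L <- spec$n_labels
  keep_a <- ds$batch == 0L
  keep_b <- ds$batch == 1L
  if (mode == "disjoint") {
    keep_a <- keep_a & lab == 0L
    keep_b <- keep_b & lab != 0L
  } else if (mode == "one_unique") {
    keep_b <- keep_b & lab != 0L
  } else {
    keep_a <- keep_a & lab != (L - 1L)
    keep_b <- keep_b & lab != 0L
  }
  strip <- function(keep) {
    d <- subset_cells(ds, which(keep))
    gene_expression_dataset(d$counts, batch = rep(0L, d$n_cells),
                            labels = d$labels, gene_ids = d$gene_ids,
                            n_batches = 1L)
  }
  list(a = strip(keep_a), b = strip(keep_b), full = sim,
       kept = list(a = which(keep_a), b = which(keep_b)))
}
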