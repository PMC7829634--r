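#' Normalize CITE-seq protein counts by two-component mixture splitting
#'
#' Antibody-derived protein counts are bimodal: a background mode and a
#' signal mode.  For each protein a two-component Gaussian mixture is fit
#' (unequal variances) and counts are shifted by the midpoint of the two
#' component means and clamped at zero:
#' `x -> max(x - (mu1 + mu2) / 2, 0)`.
#'
#' @param protein_counts Cells x proteins numeric matrix, entries >= 0.
#' @param seed Seed for the mixture fit initialization.
#' @return Matrix of the same shape with non-negative entries; attribute
#'   `midpoint` holds the per-protein cutoffs.
#' @importFrom mclust Mclust mclustBIC
#' @export
normalize_cite_proteins <- function(protein_counts, seed = 1L) {
  protein_counts <- as.matrix(protein_counts)
  if (any(protein_counts < 0)) stop("protein counts must be non-negative")
  out <- protein_counts
  mids <- numeric(ncol(protein_counts))
  pn <- colnames(protein_counts)
  if (is.null(pn)) pn <- paste0("protein", seq_len(ncol(protein_counts)))
  for (j in seq_len(ncol(protein_counts))) {
    x <- protein_counts[, j]
    if (length(unique(x)) < 2L)
      stop("protein '", pn[j], "' is single-valued; mixture fit is degenerate")
    set.seed(seed)
    fit <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    if (is.null(fit))
      stop("mixture fit failed for protein '", pn[j], "'")
    mids[j] <- mean(fit$parameters$mean)
    out[, j] <- pmax(x - mids[j], 0)
  }
  attr(out, "midpoint") <- stats::setNames(mids, pn)
  out
}

#' Normalize full-length-protocol counts by relative transcript length
#'
#' Read counts from full-length protocols scale with transcript length.  Each
#' gene's counts are divided by its relative length (gene length over the
#' mean length across genes) and the integer part is kept.  No per-cell size
#' normalization is applied; cell-level depth is left to the model's library
#' size factor.
#'
#' @param counts Cells x genes count matrix.
#' @param transcript_lengths Positive per-gene lengths.
#' @return Integer-valued matrix of the same shape.
#' @export
normalize_smartseq2_lengths <- function(counts, transcript_lengths) {
  counts <- as.matrix(counts)
  if (length(transcript_lengths) != ncol(counts))
    stop("one transcript length per gene required")
  if (any(!is.finite(transcript_lengths)) || any(transcript_lengths <= 0))
    stop("transcript lengths must be positive")
  rel <- transcript_lengths / mean(transcript_lengths)
  floor(sweep(counts, 2, rel, "/"))
}
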