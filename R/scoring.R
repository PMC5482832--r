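#' Gene pairs correlated over a sample subset
#'
#' Enumerates the unordered gene pairs whose absolute masked Pearson
#' correlation exceeds `theta` over the selected samples. Pairs whose
#' correlation is undefined (a constant vector over the mask, or fewer
#' selected samples than `min_samples`) count as not correlated.
#'
#' @param x expression matrix.
#' @param genes character vector of gene ids (>= 2).
#' @param mask logical sample mask.
#' @param theta correlation threshold in (0, 1]; strict comparison.
#' @param min_samples minimum samples for a defined correlation.
#' @return two-column character matrix of gene pairs (may have 0 rows).
#' @export
correlated_pairs <- function(x, genes, mask, theta, min_samples = 3L) {
  if (length(genes) < 2) stop("need at least two genes")
  r <- masked_cor_matrix(x[genes, , drop = FALSE], as.logical(mask), min_samples)
  hit <- abs(r) > theta
  hit[is.na(hit)] <- FALSE
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  cbind(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]])
}

#' BScore: condition-specificity of a candidate bicluster
#'
#' Let N be the set of gene pairs (within the candidate's gene set) whose
#' absolute correlation exceeds `theta` over the candidate's samples, and
#' M the analogous set over the remaining samples. BScore is the Jaccard
#' overlap |N intersect M| / |N union M|: 0 means the coexpression is
#' fully specific to the selected samples, 1 means it holds equally well
#' outside them. When both N and M are empty the score is defined as 0
#' (an unverifiable candidate is treated as maximally condition-specific;
#' the search itself never produces one, since a seed pair guarantees one
#' correlated pair). A complement with fewer than `min_samples` samples
#' makes M empty, so the score stays well-defined for biclusters spanning
#' nearly all samples.
#'
#' @inheritParams correlated_pairs
#' @return real in [0, 1].
#' @export
bscore <- function(x, genes, mask, theta, min_samples = 3L) {
  if (length(genes) < 2) stop("need at least two genes")
  mask <- as.logical(mask)
  sub <- x[genes, , drop = FALSE]
  inside <- pair_hits(masked_cor_matrix(sub, mask, min_samples), theta)
  outside <- pair_hits(masked_cor_matrix(sub, !mask, min_samples), theta)
  uni <- sum(inside | outside)
  if (uni == 0) return(0)
  sum(inside & outside) / uni
}

# upper-triangle logical "pair correlated" matrix from a correlation matrix
pair_hits <- function(r, theta) {
  hit <- abs(r) > theta
  hit[is.na(hit)] <- FALSE
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  hit
}

# bscore from two precomputed correlation matrices (same gene order),
# restricted to the member index set. Used by the search hot path.
bscore_from_cors <- function(cor_in, cor_out, members, theta) {
  inside <- pair_hits(cor_in[members, members, drop = FALSE], theta)
  outside <- pair_hits(cor_out[members, members, drop = FALSE], theta)
  uni <- sum(inside | outside)
  if (uni == 0) return(0)
  sum(inside & outside) / uni
}
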