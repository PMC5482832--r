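#' Masked Pearson correlation
#'
#' Pearson correlation between two expression vectors computed only over
#' the samples selected by a bit mask. Means and variances are taken over
#' the masked samples alone, so the value is exactly the textbook Pearson
#' coefficient of the two subset vectors.
#'
#' @param x,y numeric vectors of equal length m.
#' @param mask logical (or 0/1) vector of length m selecting samples.
#' @param min_samples minimum number of selected samples (default 3;
#'   a correlation over fewer points is not meaningful).
#' @return correlation in [-1, 1].
#' @export
#' @examples
#' masked_pearson(c(1, 2, 3, 100), c(2, 4, 6, -100), c(1, 1, 1, 0))  # 1
masked_pearson <- function(x, y, mask, min_samples = 3L) {
  if (length(x) != length(y) || length(x) != length(mask))
    stop("x, y and mask must have equal length")
  mask <- as.logical(mask)
  n <- sum(mask)
  if (n < min_samples)
    stop("mask selects ", n, " samples; at least ", min_samples, " required")
  xs <- x[mask] - sum(x[mask]) / n
  ys <- y[mask] - sum(y[mask]) / n
  sx <- sum(xs * xs)
  sy <- sum(ys * ys)
  if (sx == 0 || sy == 0)
    stop("degenerate (zero-variance) vector over the masked samples")
  r <- sum(xs * ys) / sqrt(sx * sy)
  min(1, max(-1, r))
}

# All-pairs masked correlation matrix for the rows of x over the columns
# selected by `cols` (logical or index). Rows with zero variance over the
# selection, or a selection below min_samples, yield NA entries; callers
# treat NA as "not correlated". Returned matrix keeps x's row names.
masked_cor_matrix <- function(x, cols, min_samples = 3L) {
  if (is.logical(cols)) cols <- which(cols)
  n <- length(cols)
  out <- matrix(NA_real_, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  if (n < min_samples) return(out)
  sub <- x[, cols, drop = FALSE]
  ctr <- sub - rowMeans(sub)
  ss <- rowSums(ctr * ctr)
  ok <- ss > 0
  if (!any(ok)) return(out)
  z <- ctr[ok, , drop = FALSE] / sqrt(ss[ok])
  r <- tcrossprod(z)
  r[r > 1] <- 1
  r[r < -1] <- -1
  out[ok, ok] <- r
  out
}

# Standardized rows over a column selection: tcrossprod of the result is
# the masked correlation matrix. Degenerate rows come back as NA rows.
masked_z <- function(x, cols) {
  if (is.logical(cols)) cols <- which(cols)
  sub <- x[, cols, drop = FALSE]
  ctr <- sub - rowMeans(sub)
  ss <- rowSums(ctr * ctr)
  z <- ctr / sqrt(ss)
  z[ss == 0, ] <- NA_real_
  z
}

#' Split samples into similarity pattern classes for a gene pair
#'
#' For each sample, the deviations of the two genes from their all-sample
#' means determine the pattern class: both above (up-regulated positive
#' correlation, J1), both below (down-regulated positive correlation, J2),
#' or on opposite sides (negative correlation, J3). All inequalities are
#' strict, so a sample sitting exactly at either gene's mean belongs to no
#' class.
#'
#' @param x,y expression vectors of the two genes over all samples.
#' @param mean_x,mean_y all-sample means of the two genes (defaults:
#'   computed from x and y).
#' @return list with logical masks `j1`, `j2`, `j3` (pairwise disjoint).
#' @export
split_samples <- function(x, y, mean_x = mean(x), mean_y = mean(y)) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  dx <- x - mean_x
  dy <- y - mean_y
  list(j1 = dx > 0 & dy > 0,
       j2 = dx < 0 & dy < 0,
       j3 = dx * dy < 0)
}
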