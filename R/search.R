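# Seed correlation without error signalling: NA when degenerate or the
# mask is too small. Hot path of the partner scan.
seed_cor <- function(x, y, mask, min_samples) {
  n <- sum(mask)
  if (n < min_samples) return(NA_real_)
  xs <- x[mask] - sum(x[mask]) / n
  ys <- y[mask] - sum(y[mask]) / n
  sx <- sum(xs * xs)
  sy <- sum(ys * ys)
  if (sx == 0 || sy == 0) return(NA_real_)
  min(1, max(-1, sum(xs * ys) / sqrt(sx * sy)))
}

#' Grow a bicluster gene set from a seed pair
#'
#' Starting from the seed pair, candidate genes are scanned in the
#' matrix's row order (the search uses a variability-sorted matrix, so
#' higher-variability genes are considered first). A candidate joins the
#' gene set iff its absolute masked correlation with EVERY current member
#' exceeds `theta`. The sample mask is frozen throughout growth.
#'
#' @param x expression matrix (row order defines the scan order).
#' @param seed character vector of two gene ids already known to be
#'   correlated over the mask.
#' @param mask logical sample mask, fixed during growth.
#' @param theta correlation threshold (strict).
#' @param min_samples minimum selected samples for a defined correlation.
#' @return character vector of member gene ids, seed first, then
#'   additions in scan order.
#' @export
grow_bicluster <- function(x, seed, mask, theta, min_samples = 3L) {
  mask <- as.logical(mask)
  if (sum(mask) < min_samples) stop("mask below min_samples")
  z <- masked_z(x, mask)
  members <- match(seed, rownames(x))
  if (anyNA(members)) stop("seed genes not in matrix")
  rownames(x)[grow_members(z, members, theta)]
}

# index-level growth over a standardized matrix z (tcrossprod(z) is the
# masked correlation matrix). Returns member row indices.
grow_members <- function(z, members, theta) {
  ok <- abs(z %*% t(z[members, , drop = FALSE])) > theta  # genes x members
  ok[is.na(ok)] <- FALSE
  for (p in seq_len(nrow(z))) {
    if (p %in% members) next
    if (all(ok[p, ])) {
      members <- c(members, p)
      col <- abs(z %*% z[p, ]) > theta
      col[is.na(col)] <- FALSE
      ok <- cbind(ok, col)
    }
  }
  members
}

#' Best condition-specific bicluster for one base gene
#'
#' Implements the per-base-gene search: the base gene (row `base_index`
#' of the variability-sorted matrix) is paired with every later-sorted
#' gene; each pair's samples are split into the three pattern classes
#' (up-regulated positive, down-regulated positive, negative); each class
#' whose sample count reaches `min_samples` and whose seed correlation
#' passes `theta` is grown into a candidate and scored with [bscore()].
#' The candidate with the smallest BScore below `bscore_threshold` wins;
#' BScore ties go to the larger gene set, and residual ties to the
#' first-encountered candidate (partner order, then class order J1, J2,
#' J3), which keeps the search deterministic.
#'
#' @param x variability-sorted expression matrix.
#' @param base_index row index of the base gene in `x`.
#' @param theta correlation threshold.
#' @param min_samples minimum samples per class mask.
#' @param bscore_threshold maximum admissible BScore (default 0.01).
#' @param all_means optional precomputed all-sample row means of `x`.
#' @return a [bicluster()] or NULL when no candidate passes.
#' @export
find_bicluster_for_base <- function(x, base_index, theta, min_samples = 3L,
                                    bscore_threshold = 0.01, all_means = NULL) {
  n <- nrow(x)
  if (base_index >= n) return(NULL)
  if (is.null(all_means)) all_means <- rowMeans(x)
  classes <- c("up-positive", "down-positive", "negative")
  xi <- x[base_index, ]
  best <- NULL
  best_bs <- Inf
  best_size <- 0L
  for (j in (base_index + 1L):n) {
    xj <- x[j, ]
    split <- split_samples(xi, xj, all_means[base_index], all_means[j])
    for (k in 1:3) {
      mask <- split[[k]]
      r <- seed_cor(xi, xj, mask, min_samples)
      if (is.na(r) || abs(r) <= theta) next
      z <- masked_z(x, mask)
      members <- grow_members(z, c(base_index, j), theta)
      cor_in <- tcrossprod(z[members, , drop = FALSE])
      cor_out <- masked_cor_matrix(x[members, , drop = FALSE], !mask, min_samples)
      inside <- pair_hits(cor_in, theta)
      outside <- pair_hits(cor_out, theta)
      uni <- sum(inside | outside)
      bs <- if (uni == 0) 0 else sum(inside & outside) / uni
      size <- length(members)
      if (bs < bscore_threshold &&
          (bs < best_bs || (bs == best_bs && size > best_size))) {
        best_bs <- bs
        best_size <- size
        best <- bicluster(rownames(x)[members], colnames(x)[mask], bscore = bs,
                          base_gene = rownames(x)[base_index],
                          pattern_class = classes[k])
      }
    }
  }
  best
}

#' Merge overlapping biclusters
#'
#' Single pass over the bicluster list: for each live pair sharing at
#' least one gene, the union (of both gene sets and both sample sets) is
#' adopted if its BScore stays below `bscore_threshold`; the absorbed
#' bicluster is dropped and the updated one takes part in the remaining
#' comparisons of the same pass. Merged biclusters need not retain the
#' all-pairs correlation property; only the BScore bound is guaranteed.
#' Surviving biclusters get their stored BScore recomputed on their final
#' gene and sample sets.
#'
#' @param x expression matrix.
#' @param biclusters list of [bicluster()] objects, each with BScore below
#'   the threshold.
#' @param theta correlation threshold used for the BScore pair sets.
#' @param min_samples minimum samples for a defined correlation.
#' @param bscore_threshold maximum BScore for accepting a merge.
#' @return list of surviving biclusters.
#' @export
merge_biclusters <- function(x, biclusters, theta, min_samples = 3L,
                             bscore_threshold = 0.01) {
  nb <- length(biclusters)
  if (nb < 2) return(biclusters)
  alive <- rep(TRUE, nb)
  samples_all <- colnames(x)
  for (a in seq_len(nb)) {
    if (!alive[a]) next
    for (b in seq_len(nb)) {
      if (b == a || !alive[b]) next
      A <- biclusters[[a]]
      B <- biclusters[[b]]
      if (!length(intersect(A$genes, B$genes))) next
      u_genes <- union(A$genes, B$genes)
      u_samples <- union(A$samples, B$samples)
      bs <- bscore(x, u_genes, samples_all %in% u_samples, theta, min_samples)
      if (bs < bscore_threshold) {
        biclusters[[a]] <- bicluster(u_genes, u_samples, bscore = bs,
                                     base_gene = A$base_gene,
                                     pattern_class = "merged")
        alive[b] <- FALSE
      }
    }
  }
  out <- biclusters[alive]
  lapply(out, function(b) {
    b$bscore <- bscore(x, b$genes, samples_all %in% b$samples, theta, min_samples)
    b
  })
}

#' Condition-dependent correlation subgroup (CCS) biclustering
#'
#' Runs the full search: genes are sorted by expression variability; each
#' of the first `base_number` genes seeds a per-base search
#' ([find_bicluster_for_base()]); the per-base results are merged
#' ([merge_biclusters()]). If no bicluster is found and `adaptive_theta`
#' is TRUE, the threshold is lowered by `theta_step` and the search rerun
#' until a bicluster appears or theta reaches 0.
#'
#' The search is fully deterministic: the output is a pure function of
#' the matrix and the parameters. Per-base searches are independent of
#' one another, so they may be executed in any order; results are always
#' assembled in sorted base-gene order before merging, which fixes the
#' merge order and hence the final set.
#'
#' @param x numeric expression matrix, genes x samples, unique dimnames.
#' @param theta initial correlation threshold in (0, 1] (default 0.8).
#' @param base_number number of top-variability genes to seed from;
#'   "auto" (default) uses all genes for matrices of up to 2000 genes and
#'   1000 otherwise, mirroring the cap used to restrict search time on
#'   genome-scale data. "all" forces every gene.
#' @param min_samples minimum sample count for any correlation (default 3).
#' @param adaptive_theta lower theta by `theta_step` while the result is
#'   empty (default TRUE).
#' @param bscore_threshold maximum BScore of a reported bicluster (0.01).
#' @param theta_step decrement for the adaptive threshold (0.05).
#' @param verbose print one line per base gene.
#' @return object of class `ccs_biclusters`: list with `biclusters`
#'   (list of [bicluster()]), `theta_used`, and `params`.
#' @export
#' @examples
#' syn <- generate_shift_scale(40, 20, k = 1, seed = 1)
#' res <- ccs(syn$matrix, theta = 0.8)
#' summary(res)
ccs <- function(x, theta = 0.8, base_number = "auto", min_samples = 3L,
                adaptive_theta = TRUE, bscore_threshold = 0.01,
                theta_step = 0.05, verbose = FALSE) {
  validate_expression_matrix(x)
  stopifnot(theta > 0, theta <= 1, theta_step > 0, bscore_threshold > 0)
  xs <- sort_by_variability(x)
  n <- nrow(xs)
  nb <- if (identical(base_number, "auto")) {
    if (n <= 2000L) n else 1000L
  } else if (identical(base_number, "all")) n else {
    stopifnot(is.numeric(base_number), base_number >= 1)
    min(as.integer(base_number), n)
  }
  all_means <- rowMeans(xs)
  th <- theta
  repeat {
    found <- vector("list", nb)
    for (i in seq_len(nb)) {
      found[[i]] <- find_bicluster_for_base(xs, i, th, min_samples,
                                            bscore_threshold, all_means)
      if (verbose && !is.null(found[[i]]))
        message(sprintf("base %s: %d genes, BScore %.4g",
                        rownames(xs)[i], length(found[[i]]$genes),
                        found[[i]]$bscore))
    }
    found <- found[!vapply(found, is.null, logical(1))]
    merged <- merge_biclusters(xs, found, th, min_samples, bscore_threshold)
    if (length(merged) || !adaptive_theta) break
    nxt <- round(th - theta_step, 10)
    if (nxt <= 0) break      # theta_used stays at the last theta searched
    th <- nxt
  }
  structure(list(biclusters = merged, theta_used = th,
                 params = list(theta = theta, base_number = nb,
                               min_samples = min_samples,
                               adaptive_theta = adaptive_theta,
                               bscore_threshold = bscore_threshold,
                               theta_step = theta_step)),
            class = "ccs_biclusters")
}
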