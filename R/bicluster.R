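#' Construct a bicluster
#'
#' A bicluster is a gene set I and a sample set J such that every gene
#' pair in I is correlated (absolute Pearson above the search threshold)
#' over exactly the samples J. Identifiers are stored as character
#' vectors, never positional indices, so biclusters survive matrix
#' reordering.
#'
#' @param genes character vector of gene ids (>= 2).
#' @param samples character vector of sample ids.
#' @param bscore condition-specificity score in [0, 1], or NA for planted
#'   truth biclusters where no score applies.
#' @param base_gene the gene the search was seeded from, or NA.
#' @param pattern_class one of "up-positive", "down-positive", "negative",
#'   "merged", or NA.
#' @return object of class `ccs_bicluster`.
#' @export
bicluster <- function(genes, samples, bscore = NA_real_, base_gene = NA_character_,
                      pattern_class = NA_character_) {
  stopifnot(is.character(genes), is.character(samples), length(genes) >= 2)
  structure(list(genes = genes, samples = samples,
                 bscore = as.numeric(bscore),
                 base_gene = as.character(base_gene),
                 pattern_class = as.character(pattern_class)),
            class = "ccs_bicluster")
}

#' @export
print.ccs_bicluster <- function(x, ...) {
  cat(sprintf("Bicluster: %d genes x %d samples", length(x$genes), length(x$samples)))
  if (!is.na(x$bscore)) cat(sprintf(", BScore %.4g", x$bscore))
  cat("\n")
  if (!is.na(x$base_gene))
    cat("  base gene:", x$base_gene, " class:", x$pattern_class, "\n")
  cat("  genes:  ", paste(utils::head(x$genes, 8), collapse = " "),
      if (length(x$genes) > 8) "..." else "", "\n")
  cat("  samples:", paste(utils::head(x$samples, 8), collapse = " "),
      if (length(x$samples) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
print.ccs_biclusters <- function(x, ...) {
  cat(sprintf("CCS bicluster set: %d bicluster(s), theta used = %g\n",
              length(x$biclusters), x$theta_used))
  if (length(x$biclusters)) print(summary(x))
  invisible(x)
}

#' @export
summary.ccs_biclusters <- function(object, ...) {
  bs <- object$biclusters
  data.frame(
    n_genes = vapply(bs, function(b) length(b$genes), integer(1)),
    n_samples = vapply(bs, function(b) length(b$samples), integer(1)),
    bscore = vapply(bs, function(b) b$bscore, numeric(1)),
    base_gene = vapply(bs, function(b) b$base_gene, character(1)),
    pattern_class = vapply(bs, function(b) b$pattern_class, character(1)),
    row.names = paste0("bicluster_", seq_along(bs))
  )
}

#' @export
as.data.frame.ccs_biclusters <- function(x, ...) summary(x)

#' @export
length.ccs_biclusters <- function(x) length(x$biclusters)

#' @export
`[[.ccs_biclusters` <- function(x, i) x$biclusters[[i]]

#' Heatmap of one bicluster against its source matrix
#'
#' Draws the bicluster's genes over all samples, with the bicluster's own
#' samples first, so the condition-specific block is visible on the left.
#'
#' @param x a `ccs_biclusters` object.
#' @param data the expression matrix the biclusters were found in.
#' @param which index of the bicluster to draw.
#' @param ... passed to [graphics::image()].
#' @export
plot.ccs_biclusters <- function(x, data, which = 1, ...) {
  if (!length(x$biclusters)) stop("empty bicluster set")
  b <- x$biclusters[[which]]
  samp <- c(b$samples, setdiff(colnames(data), b$samples))
  sub <- data[b$genes, samp, drop = FALSE]
  graphics::image(seq_len(ncol(sub)), seq_len(nrow(sub)), t(sub),
                  xlab = "samples (bicluster first)", ylab = "genes",
                  main = sprintf("bicluster %d: %d genes x %d samples",
                                 which, nrow(sub), length(b$samples)), ...)
  graphics::abline(v = length(b$samples) + 0.5, lwd = 2)
  invisible(x)
}
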