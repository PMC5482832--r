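#' Validate a gene expression matrix
#'
#' The package works on plain numeric matrices with genes as rows and
#' samples as columns. Row names are gene identifiers, column names are
#' sample identifiers; both must be unique and every cell must be a
#' finite number. Missing values are rejected rather than imputed.
#'
#' @param x numeric matrix, genes x samples, with unique dimnames.
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene row names and sample column names")
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(utils::head(dup_g, 5), collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(utils::head(dup_s, 5), collapse = ", "))
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite value at gene '%s', sample '%s'%s",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]],
                 if (nrow(bad) > 1) sprintf(" (and %d more)", nrow(bad) - 1L) else ""))
  invisible(x)
}

#' Per-gene standard deviation
#'
#' Standard deviation of one gene's expression over all samples, using the
#' population convention (divide by the number of samples). The same
#' convention is used for variability sorting, variance filtering and the
#' synthetic generator, so orderings are consistent throughout.
#'
#' @param x expression matrix (genes x samples).
#' @param gene gene identifier (row name). If missing, the standard
#'   deviations of all genes are returned as a named vector.
#' @return non-negative numeric.
#' @export
#' @examples
#' m <- matrix(c(5, 5, 5, 5, 1, 3, 1, 3), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("flat", "var"), paste0("s", 1:4)))
#' gene_sd(m, "flat")  # 0
#' gene_sd(m, "var")   # 1
gene_sd <- function(x, gene) {
  sds <- row_sds(x)
  if (missing(gene)) return(sds)
  if (!gene %in% rownames(x)) stop("unknown gene: ", gene)
  sds[[gene]]
}

# population sds of all rows, vectorized
row_sds <- function(x) {
  m <- ncol(x)
  mu <- rowMeans(x)
  sqrt(pmax(rowSums((x - mu)^2) / m, 0))
}

#' Reorder genes by expression variability
#'
#' Rows are sorted by standard deviation over all samples, descending,
#' with ties keeping their original relative order (stable sort). The
#' search considers high-variability genes both as base genes and as
#' augmentation candidates before low-variability ones, so this ordering
#' defines the scan order of the whole algorithm.
#'
#' @param x expression matrix.
#' @return the matrix with rows reordered; columns untouched.
#' @export
sort_by_variability <- function(x) {
  validate_expression_matrix(x)
  sds <- row_sds(x)
  ord <- order(-sds, seq_along(sds)) # explicit index tie-break: stable
  x[ord, , drop = FALSE]
}
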