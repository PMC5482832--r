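#' Remove low-variability genes
#'
#' Drops genes whose standard deviation over all samples (population
#' convention) is strictly below `min_sd`; a gene sitting exactly at the
#' cutoff is kept. Survivor order and values are unchanged. The
#' conventional cutoff for microarray intensity data is 2.0.
#'
#' @param x expression matrix.
#' @param min_sd removal cutoff (genes with sd < min_sd are removed).
#' @return filtered matrix (possibly with zero rows, with a warning).
#' @export
filter_low_variance <- function(x, min_sd = 2) {
  validate_expression_matrix(x)
  stopifnot(min_sd >= 0)
  keep <- row_sds(x) >= min_sd
  if (!any(keep)) warning("variance filter removed every gene")
  x[keep, , drop = FALSE]
}

#' Collapse duplicate genes to their most variable row
#'
#' When several rows (e.g. probe sets) map to the same gene symbol, only
#' the row with the highest standard deviation is kept; ties keep the
#' first occurrence. Row order of survivors is preserved and values are
#' untouched. The operation is idempotent.
#'
#' @param x expression matrix with probe/row ids as row names.
#' @param symbol_map named character vector mapping every row id to a
#'   gene symbol, or a two-column data.frame (id, symbol).
#' @param rename_to_symbol replace row ids by symbols in the output
#'   (default TRUE).
#' @return collapsed matrix.
#' @export
collapse_duplicates <- function(x, symbol_map, rename_to_symbol = TRUE) {
  validate_expression_matrix(x)
  if (is.data.frame(symbol_map))
    symbol_map <- stats::setNames(as.character(symbol_map[[2]]),
                                  as.character(symbol_map[[1]]))
  missing <- setdiff(rownames(x), names(symbol_map))
  if (length(missing))
    stop("symbol map does not cover: ", paste(utils::head(missing, 5), collapse = ", "))
  sym <- unname(symbol_map[rownames(x)])
  sds <- row_sds(x)
  keep <- logical(nrow(x))
  for (s in unique(sym)) {
    idx <- which(sym == s)
    keep[idx[which.max(sds[idx])]] <- TRUE   # which.max: first wins on ties
  }
  out <- x[keep, , drop = FALSE]
  if (rename_to_symbol) rownames(out) <- sym[keep]
  out
}
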