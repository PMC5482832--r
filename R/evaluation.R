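#' Similarity between two biclusters
#'
#' Jaccard index of the two biclusters' cell sets, where a bicluster's
#' cells are the (gene, sample) pairs of its submatrix. The "genes" mode
#' instead takes the Jaccard index of the gene sets only, which ignores
#' sample agreement; it is provided for cross-checking since published
#' match scores do not always state which convention was used.
#'
#' @param a,b [bicluster()] objects (or lists with `genes`/`samples`).
#' @param mode "cells" (default) or "genes".
#' @return similarity in [0, 1].
#' @export
bicluster_similarity <- function(a, b, mode = c("cells", "genes")) {
  mode <- match.arg(mode)
  gi <- length(intersect(a$genes, b$genes))
  if (mode == "genes") {
    gu <- length(union(a$genes, b$genes))
    return(if (gu == 0) 0 else gi / gu)
  }
  si <- length(intersect(a$samples, b$samples))
  inter <- gi * si
  uni <- length(a$genes) * length(a$samples) +
    length(b$genes) * length(b$samples) - inter
  if (uni == 0) 0 else inter / uni
}

as_bicluster_list <- function(x) {
  if (inherits(x, "ccs_biclusters")) x$biclusters
  else if (inherits(x, "ccs_synthetic")) x$truth
  else if (inherits(x, "ccs_bicluster")) list(x)
  else x
}

best_matches <- function(from, against, mode) {
  vapply(from, function(a) {
    if (!length(against)) return(0)
    max(vapply(against, function(b) bicluster_similarity(a, b, mode), numeric(1)))
  }, numeric(1))
}

#' Recovery: are the expected biclusters found?
#'
#' Mean, over the expected (planted) biclusters, of the best similarity
#' to any found bicluster. 1 means every expected bicluster is perfectly
#' recovered; an empty found set scores 0.
#'
#' @param found found biclusters: a `ccs_biclusters` object or a list of
#'   [bicluster()]s.
#' @param expected the expected biclusters: a `ccs_synthetic` object's
#'   truth, or a list of [bicluster()]s. Must be nonempty.
#' @param mode similarity mode, see [bicluster_similarity()].
#' @return score in [0, 1].
#' @export
recovery <- function(found, expected, mode = c("cells", "genes")) {
  mode <- match.arg(mode)
  found <- as_bicluster_list(found)
  expected <- as_bicluster_list(expected)
  if (!length(expected)) stop("expected bicluster set is empty")
  mean(best_matches(expected, found, mode))
}

#' Relevance: are the found biclusters expected?
#'
#' Mean, over the found biclusters, of the best similarity to any
#' expected bicluster; the role-symmetric counterpart of [recovery()].
#' An empty found set scores 0 by convention.
#'
#' @inheritParams recovery
#' @return score in [0, 1].
#' @export
relevance <- function(found, expected, mode = c("cells", "genes")) {
  mode <- match.arg(mode)
  found <- as_bicluster_list(found)
  expected <- as_bicluster_list(expected)
  if (!length(expected)) stop("expected bicluster set is empty")
  if (!length(found)) return(0)
  mean(best_matches(found, expected, mode))
}

#' Evaluate a found bicluster set against planted truth
#'
#' @inheritParams recovery
#' @return object of class `ccs_evaluation`: list with `recovery`,
#'   `relevance`, `per_expected_best` and `per_found_best`.
#' @export
evaluate_biclusters <- function(found, expected, mode = c("cells", "genes")) {
  mode <- match.arg(mode)
  fl <- as_bicluster_list(found)
  el <- as_bicluster_list(expected)
  if (!length(el)) stop("expected bicluster set is empty")
  pe <- best_matches(el, fl, mode)
  pf <- best_matches(fl, el, mode)
  structure(list(recovery = mean(pe),
                 relevance = if (length(pf)) mean(pf) else 0,
                 per_expected_best = pe, per_found_best = pf,
                 mode = mode),
            class = "ccs_evaluation")
}

#' @export
print.ccs_evaluation <- function(x, ...) {
  cat(sprintf("Recovery:  %.4f\nRelevance: %.4f\n(%s-level Jaccard, %d expected, %d found)\n",
              x$recovery, x$relevance, x$mode,
              length(x$per_expected_best), length(x$per_found_best)))
  invisible(x)
}
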