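# resolve a sample selection (logical mask or character ids) to logical
as_sample_mask <- function(mask, sample_ids) {
  if (is.character(mask)) {
    missing <- setdiff(mask, sample_ids)
    if (length(missing))
      stop("unknown sample id(s): ", paste(utils::head(missing, 5), collapse = ", "))
    return(sample_ids %in% mask)
  }
  mask <- as.logical(mask)
  if (length(mask) != length(sample_ids))
    stop("mask length does not match the number of samples")
  mask
}

#' Coexpression network over a sample subset
#'
#' Builds a correlation network among the given genes: an edge connects
#' two genes when their absolute masked Pearson correlation over the
#' selected samples is at least `theta` (a closed threshold, matching
#' the convention "correlation >= 0.8 or <= -0.8" of coexpression
#' figures; the bicluster search itself uses a strict threshold). Edge
#' weights are the signed correlations.
#'
#' @param x expression matrix.
#' @param genes character vector of node genes.
#' @param mask sample selection: logical mask over columns, or sample ids.
#' @param theta edge threshold on absolute correlation (default 0.8).
#' @param min_samples minimum selected samples (default 3).
#' @param roles optional named character vector of node roles (e.g.
#'   "bicluster-1", "neighbor"), attached as a node attribute.
#' @return an [igraph::graph] with edge attribute `weight` (signed
#'   correlation) and graph attributes `theta` and `condition` (the
#'   selected sample ids).
#' @export
build_network <- function(x, genes, mask, theta = 0.8, min_samples = 3L,
                          roles = NULL) {
  validate_expression_matrix(x)
  mask <- as_sample_mask(mask, colnames(x))
  if (sum(mask) < min_samples)
    stop("mask selects ", sum(mask), " samples; at least ", min_samples, " required")
  r <- masked_cor_matrix(x[genes, , drop = FALSE], mask, min_samples)
  hit <- abs(r) >= theta
  hit[is.na(hit)] <- FALSE
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  edges <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                      weight = r[idx], stringsAsFactors = FALSE)
  vertices <- data.frame(name = genes,
                         role = if (is.null(roles)) rep("member", length(genes))
                                else unname(roles[genes]),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  g <- igraph::set_graph_attr(g, "theta", theta)
  igraph::set_graph_attr(g, "condition", paste(colnames(x)[mask], collapse = ","))
}

#' Neighboring genes of a bicluster
#'
#' Genes outside the bicluster whose absolute correlation, over the given
#' samples, with at least one bicluster gene reaches `theta`.
#'
#' @param x expression matrix.
#' @param bc a [bicluster()].
#' @param mask sample selection (defaults to the bicluster's own samples).
#' @param theta closed correlation threshold (default 0.8).
#' @param min_samples minimum selected samples.
#' @return character vector of gene ids (possibly empty).
#' @export
neighboring_genes <- function(x, bc, mask = bc$samples, theta = 0.8,
                              min_samples = 3L) {
  mask <- as_sample_mask(mask, colnames(x))
  outside <- setdiff(rownames(x), bc$genes)
  if (!length(outside) || sum(mask) < min_samples) return(character(0))
  z <- masked_z(x, mask)
  r <- z[outside, , drop = FALSE] %*% t(z[bc$genes, , drop = FALSE])
  r[is.na(r)] <- 0
  outside[apply(abs(r) >= theta, 1, any)]
}

#' Per-condition edge density of biclusters
#'
#' For each condition (sample mask) and each bicluster, reports the
#' fraction of the bicluster's gene pairs whose absolute correlation over
#' that condition's samples reaches `theta`. A pre-merge bicluster has
#' density 1 over its own samples (the all-pairs property) and typically
#' much lower density over unrelated conditions — the sense in which a
#' bicluster is a condition-dependent network module.
#'
#' @param x expression matrix.
#' @param biclusters `ccs_biclusters` object or list of [bicluster()]s.
#' @param conditions named list of sample selections (logical masks or
#'   sample-id vectors).
#' @param theta closed correlation threshold (default 0.8).
#' @param min_samples minimum selected samples.
#' @return data.frame with columns `condition`, `bicluster`, `n_genes`,
#'   `density`.
#' @export
module_report <- function(x, biclusters, conditions, theta = 0.8,
                          min_samples = 3L) {
  bl <- as_bicluster_list(biclusters)
  out <- data.frame(condition = character(0), bicluster = integer(0),
                    n_genes = integer(0), density = numeric(0))
  for (cn in names(conditions)) {
    mask <- as_sample_mask(conditions[[cn]], colnames(x))
    for (bi in seq_along(bl)) {
      genes <- bl[[bi]]$genes
      r <- masked_cor_matrix(x[genes, , drop = FALSE], mask, min_samples)
      hit <- abs(r) >= theta
      hit[is.na(hit)] <- FALSE
      np <- length(genes) * (length(genes) - 1) / 2
      dens <- if (np == 0) NA_real_ else sum(hit[upper.tri(hit)]) / np
      out <- rbind(out, data.frame(condition = cn, bicluster = bi,
                                   n_genes = length(genes), density = dens))
    }
  }
  out
}

#' Write a coexpression network to disk
#'
#' Writes a weighted edge list (TSV: from, to, weight) and a GraphML file
#' with node roles as attributes.
#'
#' @param g igraph object from [build_network()].
#' @param edge_path path for the edge-list TSV.
#' @param graphml_path optional path for the GraphML export.
#' @export
write_network <- function(g, edge_path, graphml_path = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(el, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(NULL)
}
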