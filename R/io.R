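#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: a header row of sample ids, then one row per gene with the
#' gene id in the first column. GCT: the standard "#1.2" two-line header
#' followed by Name / Description columns. Duplicate identifiers and
#' missing or non-numeric cells are hard errors with diagnostics; no
#' imputation is attempted.
#'
#' @param path input file.
#' @param format "auto" (default: .gct extension selects GCT), "tsv" or
#'   "gct".
#' @return validated numeric matrix, genes x samples.
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") {
    header <- readLines(path, n = 1)
    if (!startsWith(header, "#1.2"))
      stop("not a GCT 1.2 file: ", path)
    df <- utils::read.delim(path, skip = 2, check.names = FALSE,
                            colClasses = "character")
    ids <- df[[1]]
    df <- df[, -(1:2), drop = FALSE]   # drop Name, Description
  } else {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
    ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  vals <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, colnames(df)))
  bad <- which(is.na(vals) & !is.na(as.matrix(df)), arr.ind = TRUE)
  if (length(bad))
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(df)[bad[1, 2]]))
  rownames(vals) <- ids
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits, so a write/read round
#' trip reproduces the matrix bit-identically.
#'
#' @param x expression matrix.
#' @param path output file.
#' @export
write_matrix <- function(x, path) {
  validate_expression_matrix(x)
  txt <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  lines <- c(paste(c("gene", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(txt, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(NULL)
}

.bicluster_format_version <- 1L

#' Write a bicluster set as JSON
#'
#' The document stores gene and sample identifiers (never indices), the
#' BScore, base gene and pattern class of each bicluster, plus the theta
#' actually used; it round-trips losslessly through [read_biclusters()].
#'
#' @param set `ccs_biclusters` object, or a list of [bicluster()]s (e.g.
#'   a synthetic truth set), in which case `theta_used` is recorded as NA.
#' @param path output file.
#' @export
write_biclusters <- function(set, path) {
  bl <- as_bicluster_list(set)
  doc <- list(
    format_version = .bicluster_format_version,
    theta_used = if (inherits(set, "ccs_biclusters")) set$theta_used else NA,
    biclusters = lapply(bl, function(b)
      list(genes = as.list(b$genes), samples = as.list(b$samples),
           bscore = b$bscore, base_gene = b$base_gene,
           pattern_class = b$pattern_class))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(NULL)
}

#' Read a bicluster set from JSON
#'
#' @param path file written by [write_biclusters()].
#' @return `ccs_biclusters` object.
#' @export
read_biclusters <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$format_version) ||
      doc$format_version != .bicluster_format_version)
    stop("unsupported bicluster document version: ",
         if (is.null(doc$format_version)) "missing" else doc$format_version)
  bl <- lapply(doc$biclusters, function(r)
    bicluster(genes = unlist(r$genes), samples = unlist(r$samples),
              bscore = if (is.null(r$bscore)) NA_real_ else r$bscore,
              base_gene = if (is.null(r$base_gene)) NA_character_ else r$base_gene,
              pattern_class = if (is.null(r$pattern_class)) NA_character_
                              else r$pattern_class))
  structure(list(biclusters = bl,
                 theta_used = if (is.null(doc$theta_used)) NA_real_
                              else as.numeric(doc$theta_used),
                 params = list()),
            class = "ccs_biclusters")
}
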