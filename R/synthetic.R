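# run expr with a local RNG stream; the caller's .Random.seed is untouched
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# draw k disjoint row/col blocks; sizes jittered +-20% around n/(k+2) rows
# and m/(k+1) cols unless explicit ranges are given. Gene/sample indices
# are assigned by shuffling, so planted blocks are not contiguous.
plan_blocks <- function(n_rows, n_cols, k, row_range, col_range) {
  if (k == 0) return(list())
  if (is.null(row_range)) {
    base <- n_rows / (k + 2)
    row_range <- c(max(2, floor(base * 0.8)), max(2, ceiling(base * 1.2)))
  }
  if (is.null(col_range)) {
    base <- n_cols / (k + 1)
    col_range <- c(max(3, floor(base * 0.8)), max(3, ceiling(base * 1.2)))
  }
  draw_sizes <- function(rng, k) {
    choices <- seq(rng[1], rng[2])
    if (length(choices) == 1) rep(choices, k)  # sample(n, ...) trap
    else sample(choices, k, replace = TRUE)
  }
  r_sizes <- draw_sizes(row_range, k)
  c_sizes <- draw_sizes(col_range, k)
  if (sum(r_sizes) > n_rows || sum(c_sizes) > n_cols)
    stop(sprintf("cannot place %d disjoint blocks (%d rows, %d cols needed) in a %dx%d matrix",
                 k, sum(r_sizes), sum(c_sizes), n_rows, n_cols))
  row_pool <- sample.int(n_rows)
  col_pool <- sample.int(n_cols)
  blocks <- vector("list", k)
  ro <- co <- 0L
  for (b in seq_len(k)) {
    blocks[[b]] <- list(rows = sort(row_pool[ro + seq_len(r_sizes[b])]),
                        cols = sort(col_pool[co + seq_len(c_sizes[b])]))
    ro <- ro + r_sizes[b]
    co <- co + c_sizes[b]
  }
  blocks
}

finish_dataset <- function(values, blocks, spec) {
  dimnames(values) <- list(paste0("g", seq_len(nrow(values))),
                           paste0("s", seq_len(ncol(values))))
  truth <- lapply(seq_along(blocks), function(b) {
    bicluster(rownames(values)[blocks[[b]]$rows],
              colnames(values)[blocks[[b]]$cols],
              base_gene = NA_character_, pattern_class = NA_character_)
  })
  structure(list(matrix = values, truth = truth, spec = spec),
            class = "ccs_synthetic")
}

#' @export
print.ccs_synthetic <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d genes x %d samples, %d planted %s bicluster(s), seed %s\n",
              nrow(x$matrix), ncol(x$matrix), length(x$truth),
              x$spec$type, format(x$spec$seed)))
  invisible(x)
}

#' Synthetic dataset with planted constant biclusters
#'
#' Background cells are drawn from Normal(0, bg_sd); each planted block
#' is filled with `signal_value` plus Normal(0, noise_sd) noise. Blocks
#' are pairwise row- and column-disjoint, with sizes jittered around
#' n_rows/(k+2) by n_cols/(k+1) unless explicit ranges are supplied.
#' Regeneration from the same seed is bit-identical.
#'
#' @param n_rows,n_cols matrix dimensions.
#' @param k number of planted biclusters.
#' @param row_range,col_range integer c(min, max) block sizes, or NULL
#'   for the default jittered sizing.
#' @param bg_sd background standard deviation (default 1).
#' @param signal_value constant level of planted blocks (default 5).
#' @param noise_sd within-block noise standard deviation (default 0.1).
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return object of class `ccs_synthetic`: list with `matrix`, `truth`
#'   (list of planted [bicluster()]s) and `spec`.
#' @export
generate_constant <- function(n_rows, n_cols, k, row_range = NULL,
                              col_range = NULL, bg_sd = 1, signal_value = 5,
                              noise_sd = 0.1, seed = 1L) {
  with_local_seed(seed, {
    blocks <- plan_blocks(n_rows, n_cols, k, row_range, col_range)
    values <- matrix(stats::rnorm(n_rows * n_cols, 0, bg_sd), n_rows, n_cols)
    for (b in blocks)
      values[b$rows, b$cols] <- signal_value +
        stats::rnorm(length(b$rows) * length(b$cols), 0, noise_sd)
    finish_dataset(values, blocks,
                   list(type = "constant", n_rows = n_rows, n_cols = n_cols,
                        k = k, bg_sd = bg_sd, signal_value = signal_value,
                        noise_sd = noise_sd, seed = seed))
  })
}

#' Synthetic dataset with planted shift-scale biclusters
#'
#' Each planted block is built from a base row of Normal(0, 1) values of
#' the block's width; every block row is an affine transform
#' scale * base + shift of that base row plus Normal(0, noise_sd) noise.
#' Scales are drawn from `scale_range` with probability `neg_prob` of a
#' sign flip (planting negative-correlation structure); shifts come from
#' `shift_range`. With noise_sd = 0 all within-block row pairs correlate
#' at exactly +/-1 over the block's columns.
#'
#' @inheritParams generate_constant
#' @param scale_range c(min, max) of the positive scale magnitude.
#' @param shift_range c(min, max) of the additive shift.
#' @param neg_prob probability that a row's scale is negated (default 0.2).
#' @return object of class `ccs_synthetic`.
#' @export
generate_shift_scale <- function(n_rows, n_cols, k, row_range = NULL,
                                 col_range = NULL, bg_sd = 1,
                                 scale_range = c(0.5, 2),
                                 shift_range = c(-2, 2), noise_sd = 0.1,
                                 neg_prob = 0.2, seed = 1L) {
  with_local_seed(seed, {
    blocks <- plan_blocks(n_rows, n_cols, k, row_range, col_range)
    values <- matrix(stats::rnorm(n_rows * n_cols, 0, bg_sd), n_rows, n_cols)
    for (b in blocks) {
      w <- length(b$cols)
      base <- stats::rnorm(w)
      for (r in b$rows) {
        sc <- stats::runif(1, scale_range[1], scale_range[2])
        if (stats::runif(1) < neg_prob) sc <- -sc
        sh <- stats::runif(1, shift_range[1], shift_range[2])
        values[r, b$cols] <- sc * base + sh + stats::rnorm(w, 0, noise_sd)
      }
    }
    finish_dataset(values, blocks,
                   list(type = "shift-scale", n_rows = n_rows, n_cols = n_cols,
                        k = k, bg_sd = bg_sd, scale_range = scale_range,
                        shift_range = shift_range, noise_sd = noise_sd,
                        neg_prob = neg_prob, seed = seed))
  })
}

# the five benchmark presets: name -> type, rows, cols, k. SS.200.5 is
# named like a shift-scale set but is a constant-type benchmark; the
# preset follows its declared type.
.ccs_presets <- list(
  CNST.100.3 = list(type = "constant",    n_rows = 100, n_cols = 75,  k = 3),
  SS.150.4   = list(type = "shift-scale", n_rows = 150, n_cols = 100, k = 4),
  SS.200.5   = list(type = "constant",    n_rows = 200, n_cols = 120, k = 5),
  SS.200.6   = list(type = "shift-scale", n_rows = 200, n_cols = 120, k = 6),
  SS.250.7   = list(type = "shift-scale", n_rows = 250, n_cols = 120, k = 7)
)

#' Named synthetic benchmark presets
#'
#' Dispatches to [generate_constant()] or [generate_shift_scale()] with
#' the benchmark dimensions and bicluster counts of the five standard
#' synthetic datasets (CNST.100.3, SS.150.4, SS.200.5, SS.200.6,
#' SS.250.7). Note that SS.200.5, despite its name, is a constant-type
#' benchmark. Additional arguments override the generator defaults.
#'
#' @param name one of the five preset names.
#' @param seed RNG seed.
#' @param ... overrides passed to the generator.
#' @return object of class `ccs_synthetic`.
#' @export
#' @examples
#' syn <- ccs_preset("CNST.100.3", seed = 1)
#' dim(syn$matrix)
ccs_preset <- function(name, seed = 1L, ...) {
  if (!name %in% names(.ccs_presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.ccs_presets), collapse = ", "))
  p <- .ccs_presets[[name]]
  gen <- if (p$type == "constant") generate_constant else generate_shift_scale
  gen(n_rows = p$n_rows, n_cols = p$n_cols, k = p$k, seed = seed, ...)
}
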