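# Independent brute-force oracles. These deliberately avoid the package's
# vectorized internals (standardized cross-products, cached correlation
# matrices): every quantity is recomputed from the textbook formula on
# explicitly subset vectors, and the search replays the published loop
# structure literally. Agreement between the package and these replays is
# what the oracle-equivalence tests assert.

# textbook Pearson on explicitly subset vectors; NA when undefined
oracle_pearson <- function(x, y, mask, min_samples = 3) {
  xs <- x[as.logical(mask)]
  ys <- y[as.logical(mask)]
  if (length(xs) < min_samples) return(NA_real_)
  dx <- xs - mean(xs)
  dy <- ys - mean(ys)
  if (sum(dx^2) == 0 || sum(dy^2) == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# per-sample sign enumeration of the three pattern classes
oracle_split <- function(x, y, mx = mean(x), my = mean(y)) {
  m <- length(x)
  j1 <- j2 <- j3 <- logical(m)
  for (s in seq_len(m)) {
    a <- x[s] - mx
    b <- y[s] - my
    if (a > 0 && b > 0) j1[s] <- TRUE
    else if (a < 0 && b < 0) j2[s] <- TRUE
    else if (a * b < 0) j3[s] <- TRUE
  }
  list(j1 = j1, j2 = j2, j3 = j3)
}

# exhaustive pair enumeration; returns sorted "a|b" keys
oracle_pairs <- function(x, genes, mask, theta, min_samples = 3) {
  keys <- character(0)
  if (length(genes) >= 2) {
    cmb <- utils::combn(sort(genes), 2)
    for (p in seq_len(ncol(cmb))) {
      r <- oracle_pearson(x[cmb[1, p], ], x[cmb[2, p], ], mask, min_samples)
      if (!is.na(r) && abs(r) > theta)
        keys <- c(keys, paste(cmb[1, p], cmb[2, p], sep = "|"))
    }
  }
  sort(keys)
}

oracle_bscore <- function(x, genes, mask, theta, min_samples = 3) {
  n_in <- oracle_pairs(x, genes, mask, theta, min_samples)
  m_out <- oracle_pairs(x, genes, !as.logical(mask), theta, min_samples)
  uni <- union(n_in, m_out)
  if (!length(uni)) return(0)
  length(intersect(n_in, m_out)) / length(uni)
}

# literal replay of the per-base search (partner scan, rule split, greedy
# augmentation in row order, incumbent update with smallest-BScore /
# larger-set preference)
oracle_find_base <- function(x, i, theta, min_samples = 3, bound = 0.01) {
  n <- nrow(x)
  ids <- rownames(x)
  if (i >= n) return(NULL)
  best <- NULL
  best_bs <- Inf
  best_size <- 0
  for (j in (i + 1):n) {
    sp <- oracle_split(x[i, ], x[j, ])
    for (k in 1:3) {
      mask <- sp[[k]]
      if (sum(mask) < min_samples) next
      r <- oracle_pearson(x[i, ], x[j, ], mask, min_samples)
      if (is.na(r) || abs(r) <= theta) next
      members <- c(i, j)
      for (p in seq_len(n)) {
        if (p %in% members) next
        ok <- TRUE
        for (q in members) {
          rq <- oracle_pearson(x[p, ], x[q, ], mask, min_samples)
          if (is.na(rq) || abs(rq) <= theta) { ok <- FALSE; break }
        }
        if (ok) members <- c(members, p)
      }
      bs <- oracle_bscore(x, ids[members], mask, theta, min_samples)
      if (bs < bound &&
          (bs < best_bs || (bs == best_bs && length(members) > best_size))) {
        best_bs <- bs
        best_size <- length(members)
        best <- list(genes = ids[members], samples = colnames(x)[mask],
                     bscore = bs, class = k)
      }
    }
  }
  best
}

# literal replay of the merge pass: doubly nested loop over the (updated)
# list, union adoption under the BScore bound, in-place update
oracle_merge <- function(x, sets, theta, min_samples = 3, bound = 0.01) {
  nb <- length(sets)
  alive <- rep(TRUE, nb)
  for (a in seq_len(nb)) {
    if (!alive[a]) next
    for (b in seq_len(nb)) {
      if (b == a || !alive[b]) next
      if (!length(intersect(sets[[a]]$genes, sets[[b]]$genes))) next
      ug <- union(sets[[a]]$genes, sets[[b]]$genes)
      us <- union(sets[[a]]$samples, sets[[b]]$samples)
      if (oracle_bscore(x, ug, colnames(x) %in% us, theta, min_samples) < bound) {
        sets[[a]]$genes <- ug
        sets[[a]]$samples <- us
        alive[b] <- FALSE
      }
    }
  }
  out <- sets[alive]
  lapply(out, function(s) {
    s$bscore <- oracle_bscore(x, s$genes, colnames(x) %in% s$samples,
                              theta, min_samples)
    s
  })
}

# random gene x sample matrix with unique ids
rand_matrix <- function(n, m, sd = 1) {
  matrix(stats::rnorm(n * m, 0, sd), n, m,
         dimnames = list(paste0("g", seq_len(n)), paste0("s", seq_len(m))))
}
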