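make_affine_copies <- function(n_genes, base, noise = 0) {
  m <- length(base)
  vals <- t(sapply(seq_len(n_genes), function(i)
    i * base + i + rnorm(m, 0, noise)))
  dimnames(vals) <- list(paste0("g", seq_len(n_genes)), paste0("s", seq_len(m)))
  vals
}

test_that("correlated_pairs finds all pairs among affine copies", {
  x <- make_affine_copies(3, c(1, 4, 2, 8, 5, 7))
  p <- correlated_pairs(x, rownames(x), rep(TRUE, 6), theta = 0.8)
  expect_equal(nrow(p), 3)
})

test_that("a mask below min_samples yields no correlated pairs", {
  x <- make_affine_copies(3, c(1, 4, 2, 8, 5, 7))
  p <- correlated_pairs(x, rownames(x), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                        theta = 0.8)
  expect_equal(nrow(p), 0)
})

test_that("correlated_pairs agrees with exhaustive pair enumeration", {
  set.seed(31)
  for (rep in 1:10) {
    x <- rand_matrix(6, 9)
    mask <- rep(FALSE, 9)
    mask[sample(9, sample(3:7, 1))] <- TRUE
    got <- correlated_pairs(x, rownames(x), mask, theta = 0.8)
    keys <- if (nrow(got)) sort(apply(apply(got, 1, sort), 2, paste, collapse = "|"))
            else character(0)
    expect_identical(keys, oracle_pairs(x, rownames(x), mask, 0.8))
  }
})

test_that("bscore matches hand-constructed N and M sets", {
  # 4 genes: all 6 pairs correlated over the first six samples; over the
  # remaining six, genes 1-2 stay correlated (shared profile) while genes
  # 3-4 follow patterns nearly orthogonal to everything. N = 6 pairs,
  # M = {g1-g2}, so BScore = |N.M|/|NuM| = 1/6.
  base <- c(1, 4, 2, 8, 5, 7)
  w <- c(1, 2, 3, 4, 5, 6)
  x <- rbind(g1 = c(1 * base + 1, w),
             g2 = c(2 * base + 2, 2 * w),
             g3 = c(3 * base + 3, c(1, -1, 1, -1, 1, -1)),
             g4 = c(4 * base + 4, c(-1, 1, 1, -1, -1, 1)))
  colnames(x) <- paste0("s", 1:12)
  mask <- rep(c(TRUE, FALSE), each = 6)
  expect_equal(bscore(x, rownames(x), mask, theta = 0.8), 1 / 6)
  expect_equal(oracle_bscore(x, rownames(x), mask, 0.8), 1 / 6)
})

test_that("bscore hits 0 for fully condition-specific sets and 1 for unspecific ones", {
  set.seed(41)
  base <- rnorm(6)
  inside <- make_affine_copies(4, base)
  outside_noise <- rand_matrix(4, 6)
  x <- cbind(inside, outside_noise)
  colnames(x) <- paste0("s", 1:12)
  mask <- rep(c(TRUE, FALSE), each = 6)
  expect_equal(bscore(x, rownames(x), mask, theta = 0.95), 0)

  both <- cbind(inside, 2 * inside + 1)
  colnames(both) <- paste0("s", 1:12)
  expect_equal(bscore(both, rownames(both), mask, theta = 0.8), 1)
})

test_that("bscore agrees with the brute-force oracle and stays in [0,1]", {
  set.seed(53)
  for (rep in 1:15) {
    x <- rand_matrix(5, 10)
    mask <- rep(FALSE, 10)
    mask[sample(10, sample(3:7, 1))] <- TRUE
    b <- bscore(x, rownames(x), mask, theta = 0.5)
    expect_gte(b, 0)
    expect_lte(b, 1)
    expect_equal(b, oracle_bscore(x, rownames(x), mask, 0.5))
  }
})

test_that("bscore is invariant to gene order and within-side sample shuffles", {
  set.seed(61)
  x <- rand_matrix(5, 12)
  mask <- rep(c(TRUE, FALSE), each = 6)
  b0 <- bscore(x, rownames(x), mask, theta = 0.5)
  expect_equal(bscore(x, sample(rownames(x)), mask, theta = 0.5), b0)
  perm <- c(sample(1:6), sample(7:12))
  expect_equal(bscore(x[, perm], rownames(x), mask[perm], theta = 0.5), b0)
})

test_that("for an all-pairs bicluster, bscore equals |M| / C(|I|,2)", {
  set.seed(71)
  syn <- generate_shift_scale(20, 14, k = 1, noise_sd = 0, seed = 4)
  tr <- syn$truth[[1]]
  mask <- colnames(syn$matrix) %in% tr$samples
  m_set <- oracle_pairs(syn$matrix, tr$genes, !mask, 0.8)
  n_set <- oracle_pairs(syn$matrix, tr$genes, mask, 0.8)
  expect_equal(length(n_set), choose(length(tr$genes), 2))  # noise-free block
  expect_equal(bscore(syn$matrix, tr$genes, mask, theta = 0.8),
               length(m_set) / choose(length(tr$genes), 2))
})
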