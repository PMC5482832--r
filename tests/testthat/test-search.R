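test_that("sort_by_variability sorts descending with stable ties", {
  m <- rbind(a = c(0, 0.1, 0, 0.1), b = c(0, 5, 0, 5), c = c(0, 2, 0, 2))
  colnames(m) <- paste0("s", 1:4)
  expect_equal(rownames(sort_by_variability(m)), c("b", "c", "a"))

  tied <- rbind(first = c(1, 3), second = c(2, 4), third = c(0, 0))
  colnames(tied) <- c("s1", "s2")
  expect_equal(rownames(sort_by_variability(tied)), c("first", "second", "third"))

  set.seed(13)
  r <- rand_matrix(50, 8)
  sds <- apply(r, 1, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(rownames(sort_by_variability(r)),
               rownames(r)[order(-sds, seq_along(sds))])
})

test_that("grow_bicluster keeps a lone seed pair and absorbs affine families", {
  set.seed(19)
  x <- rand_matrix(6, 10)
  x["g2", ] <- 3 * x["g1", ] + 1          # only g1-g2 mutually correlated
  got <- grow_bicluster(x, c("g1", "g2"), rep(TRUE, 10), theta = 0.95)
  expect_setequal(got, c("g1", "g2"))

  base <- rnorm(10)
  fam <- t(sapply(1:5, function(i) i * base + i))
  dimnames(fam) <- list(paste0("g", 1:5), paste0("s", 1:10))
  expect_setequal(grow_bicluster(fam, c("g1", "g2"), rep(TRUE, 10), theta = 0.8),
                  paste0("g", 1:5))
})

test_that("grow_bicluster recovers a planted clique and replays the greedy scan", {
  set.seed(29)
  x <- rand_matrix(10, 12)
  base <- rnorm(12)
  clique <- c("g2", "g5", "g7", "g9")
  for (i in seq_along(clique))
    x[clique[i], ] <- (0.5 + i / 4) * base + rnorm(12, 0, 0.05)
  got <- grow_bicluster(x, c("g2", "g5"), rep(TRUE, 12), theta = 0.8)
  expect_setequal(got, clique)
  # independent replay of the same scan order
  members <- c(2, 5)
  for (p in setdiff(1:10, members)) {
    ok <- all(vapply(members, function(q)
      abs(oracle_pearson(x[p, ], x[q, ], rep(TRUE, 12))) > 0.8, logical(1)))
    if (ok) members <- c(members, p)
  }
  expect_identical(got, rownames(x)[members])
})

test_that("per-base selection prefers smaller BScore, then larger gene sets", {
  set.seed(37)
  # planted 4-gene clique on half the samples; the base search must pick it
  x <- rand_matrix(12, 10)
  base <- rnorm(5)
  for (i in 1:4) x[i, 1:5] <- i * base + i + rnorm(5, 0, 0.01)
  xs <- sort_by_variability(x)
  got <- find_bicluster_for_base(xs, 1L, theta = 0.8)
  ora <- oracle_find_base(xs, 1L, 0.8)
  if (is.null(ora)) {
    expect_null(got)
  } else {
    expect_identical(got$genes, ora$genes)
    expect_identical(got$samples, ora$samples)
    expect_equal(got$bscore, ora$bscore)
  }
})

test_that("a base gene uncorrelated with everything yields NULL", {
  set.seed(43)
  x <- rand_matrix(8, 20)
  xs <- sort_by_variability(x)
  # theta so high that no random pair passes
  expect_null(find_bicluster_for_base(xs, 1L, theta = 0.9999))
})

test_that("merge keeps disjoint sets, deduplicates identical ones, honors the bound", {
  set.seed(47)
  base1 <- rnorm(6); base2 <- rnorm(6)
  x <- rand_matrix(12, 18)
  for (i in 1:4) x[i, 1:6] <- i * base1 + rnorm(6, 0.01)
  for (i in 5:8) x[i, 7:12] <- i * base2 + rnorm(6, 0.01)
  ids <- rownames(x); ss <- colnames(x)
  b1 <- bicluster(ids[1:4], ss[1:6], bscore = 0)
  b2 <- bicluster(ids[5:8], ss[7:12], bscore = 0)
  m <- merge_biclusters(x, list(b1, b2), theta = 0.8)
  expect_equal(length(m), 2)          # gene-disjoint: both survive
  expect_setequal(m[[1]]$genes, b1$genes)

  m2 <- merge_biclusters(x, list(b1, b1), theta = 0.8)
  expect_equal(length(m2), 1)         # identical sets collapse to one
  expect_setequal(m2[[1]]$genes, b1$genes)
  expect_setequal(m2[[1]]$samples, b1$samples)
})

test_that("the merge pass replays the literal nested loops on a chain", {
  set.seed(59)
  for (rep in 1:5) {
    x <- rand_matrix(10, 12)
    # three overlapping gene sets over related sample windows
    sets <- list(
      bicluster(rownames(x)[1:4], colnames(x)[1:6], bscore = 0),
      bicluster(rownames(x)[3:6], colnames(x)[4:9], bscore = 0),
      bicluster(rownames(x)[6:9], colnames(x)[7:12], bscore = 0)
    )
    got <- merge_biclusters(x, sets, theta = 0.5)
    ora <- oracle_merge(x, lapply(sets, function(b)
      list(genes = b$genes, samples = b$samples)), 0.5)
    expect_equal(length(got), length(ora))
    for (i in seq_along(got)) {
      expect_identical(got[[i]]$genes, ora[[i]]$genes)
      expect_identical(got[[i]]$samples, ora[[i]]$samples)
      expect_equal(got[[i]]$bscore, ora[[i]]$bscore)
    }
  }
})

test_that("pure noise yields nothing once masks are large enough to be meaningful", {
  # at min_samples = 3 the sign rules produce 3-point masks whose
  # correlations pass even extreme thresholds by chance, so the guarantee
  # of emptiness on noise only holds with a stricter mask-size floor
  set.seed(67)
  x <- rand_matrix(20, 10)
  res <- ccs(x, theta = 0.99, min_samples = 5L, adaptive_theta = FALSE)
  expect_s3_class(res, "ccs_biclusters")
  expect_equal(length(res$biclusters), 0)
  expect_equal(res$theta_used, 0.99)
  # the permissive default does find sign-conditioned chance structure on
  # the same noise, which is the documented reason for the floor above
  res3 <- ccs(x, theta = 0.99, adaptive_theta = FALSE)
  expect_gt(length(res3$biclusters), 0)
})

test_that("ccs recovers the genes of a planted shift-scale block", {
  syn <- generate_shift_scale(36, 16, k = 1, noise_sd = 0.05, seed = 8,
                              row_range = c(6, 6), col_range = c(6, 6))
  res <- ccs(syn$matrix, theta = 0.8, adaptive_theta = FALSE)
  expect_gt(length(res$biclusters), 0)
  planted <- syn$truth[[1]]$genes
  covered <- vapply(res$biclusters, function(b)
    length(intersect(b$genes, planted)), integer(1))
  expect_gte(max(covered), length(planted))
})

test_that("adaptive theta steps down until biclusters appear", {
  syn <- generate_shift_scale(30, 14, k = 1, noise_sd = 0, seed = 10,
                              scale_range = c(0.9, 1.1), neg_prob = 0)
  # noise-free planted block exists, so some theta must succeed
  res <- ccs(syn$matrix, theta = 0.999, adaptive_theta = TRUE)
  expect_gt(length(res$biclusters), 0)
  expect_lte(res$theta_used, 0.999)
})

test_that("the search is a pure function of matrix and parameters", {
  syn <- generate_constant(30, 20, k = 1, seed = 12)
  r1 <- ccs(syn$matrix, theta = 0.8, adaptive_theta = FALSE)
  r2 <- ccs(syn$matrix, theta = 0.8, adaptive_theta = FALSE)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("raising theta does not enlarge growth from the same seed and mask", {
  set.seed(83)
  for (rep in 1:10) {
    x <- rand_matrix(10, 12)
    base <- rnorm(12)
    for (i in 1:4) x[i, ] <- i * base + rnorm(12, 0, 0.3)
    mask <- rep(TRUE, 12)
    lo <- grow_bicluster(x, c("g1", "g2"), mask, theta = 0.5)
    hi <- grow_bicluster(x, c("g1", "g2"), mask, theta = 0.7)
    expect_lte(length(hi), length(lo))
  }
})
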