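test_that("uncentered SVD fractions follow closed forms and Eckart-Young", {
  # rank-1 matrix: all variance on the first dimension
  X1 <- outer(1:5, c(2, 3, 4))
  f <- svd_variance(X1)$variance_fractions
  expect_equal(f[1], 1, tolerance = 1e-12)
  # orthogonal columns with norms 3 and 4
  X2 <- cbind(c(3, 0, 0), c(0, 4, 0))
  f2 <- svd_variance(X2)$variance_fractions
  expect_equal(sort(f2), c(9, 16) / 25)
  # Eckart-Young: truncation error at each d equals sqrt(tail sum of s^2)
  set.seed(1)
  X <- matrix(rnorm(50 * 10), 50, 10)
  sv <- svd_variance(X)
  expect_equal(sum(sv$variance_fractions), 1, tolerance = 1e-10)
  s <- sv$singular_values
  for (d in c(1, 3, 7)) {
    Xd <- sv$left_vectors[, 1:d, drop = FALSE] %*%
      (s[1:d] * t(sv$right_vectors[, 1:d, drop = FALSE]))
    expect_equal(sqrt(sum((X - Xd)^2)), sqrt(sum(s[(d + 1):10]^2)),
                 tolerance = 1e-10)
  }
  expect_error(svd_variance(matrix(c(1, NA), 1)), "finite")
})

test_that("singular values are invariant to common permutations and sign flips", {
  set.seed(2)
  X <- matrix(rnorm(30 * 6), 30, 6)
  s0 <- svd_variance(X)$singular_values
  expect_equal(svd_variance(X[sample(30), ])$singular_values, s0, tolerance = 1e-10)
  expect_equal(svd_variance(X[, sample(6)])$singular_values, s0, tolerance = 1e-10)
  flip <- X %*% diag(c(1, -1, 1, -1, -1, 1))
  expect_equal(svd_variance(flip)$singular_values, s0, tolerance = 1e-10)
})

test_that("the dimension rule reads CI separation contiguously by default", {
  expect_equal(reproducible_dimension(c(10, 5, 4.5), c(11, 6, 5.5)), 1L)
  expect_equal(reproducible_dimension(c(10, 5, 2, 1.9), c(11, 6, 3, 2.5)), 2L)
  expect_equal(reproducible_dimension(c(10, 11), c(12, 13)), 0L)
  # the alternative reading picks the last separated pair
  lows <- c(10, 9, 5); highs <- c(12, 11, 6)
  expect_equal(reproducible_dimension(lows, highs), 0L)
  expect_equal(reproducible_dimension(lows, highs, rule = "last"), 2L)
})

test_that("bootstrap SVD is deterministic and warns on tiny B", {
  dm <- planted_lowrank_dataset(100, 8, 1, 0.7, 0.2, seed = 3)
  b1 <- bootstrap_svd(dm, B = 150, seed = 5)
  b2 <- bootstrap_svd(dm, B = 150, seed = 5)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  expect_warning(bootstrap_svd(dm, B = 50, seed = 5), "B < 100")
  expect_error(bootstrap_svd(data_matrix(matrix(1:4, 2), c("a", "a"))),
               "3 distinct")
  expect_equal(b1$reproducible_dim, 1L)
  expect_equal(sum(b1$variance_fractions), 1, tolerance = 1e-10)
  # orthonormal left vectors
  U <- b1$left_vectors
  expect_lt(max(abs(crossprod(U) - diag(ncol(U)))), 1e-10)
})

test_that("average projection commutes with averaging and respects source filters", {
  set.seed(6)
  X <- matrix(rnorm(40 * 6), 40, 6)
  dm <- data_matrix(X, subject = paste0("S", rep(1:3, each = 2)),
                    source = rep(c("empirical", "sim"), 3))
  u <- svd_variance(X)$left_vectors[, 1]
  # single column: orthogonal projection
  one <- data_matrix(X[, 1, drop = FALSE], "S1")
  expect_equal(average_projection(one, u), drop(crossprod(u, X[, 1])) * u)
  # projection of mean equals mean of projections
  expect_equal(average_projection(dm, u),
               drop(crossprod(u, rowMeans(X))) * u, tolerance = 1e-12)
  # source filter equals direct computation on the submatrix
  emp <- X[, dm$source == "empirical", drop = FALSE]
  sub <- data_matrix(emp, subject = dm$subject[dm$source == "empirical"])
  expect_equal(average_projection(dm, u, source_filter = "empirical"),
               average_projection(sub, u))
  expect_error(average_projection(dm, u, source_filter = "nope"), "matches no")
})

test_that("permutation controls destroy structure exactly when they should", {
  cohort <- rank1_matrix_cohort(12, 8, seed = 7)
  atlas <- generate_atlas(12)
  n_links <- choose(12, 2)
  # forced identity permutation changes nothing
  ident <- permute_dataset(cohort, atlas, mode = "links",
                           permutations = rep(list(seq_len(n_links)), 8))
  X0 <- vapply(cohort, function(m) as.numeric(vectorize_upper(m, atlas)),
               numeric(n_links))
  expect_equal(ident$X, X0, ignore_attr = TRUE)
  # a common permutation leaves all singular values unchanged
  p <- sample(n_links)
  common <- permute_dataset(cohort, atlas, mode = "links",
                            permutations = rep(list(p), 8))
  expect_equal(svd_variance(common$X)$singular_values,
               svd_variance(X0)$singular_values, tolerance = 1e-10)
  # independent per-subject permutations break the rank-1 structure
  for (mode in c("links", "regions", "within_hemisphere")) {
    perm <- permute_dataset(cohort, atlas, mode = mode, seed = 8)
    b <- bootstrap_svd(perm, B = 150, seed = 9)
    expect_equal(b$reproducible_dim, 0L)
  }
  # the unpermuted cohort is rank-1 reproducible
  b0 <- bootstrap_svd(data_matrix(X0, names(cohort)), B = 150, seed = 9)
  expect_equal(b0$reproducible_dim, 1L)
})

test_that("within-hemisphere permutation preserves homotopic pairing", {
  atlas <- generate_atlas(10)
  gt <- generate_ground_truth_sc(atlas, density_inter = 0, homotopic_weight = 0.7,
                                 seed = 10)
  perm <- permute_dataset(list(S1 = gt$weights, S2 = gt$weights, S3 = gt$weights),
                          atlas, mode = "within_hemisphere", seed = 11)
  idx <- scfc:::pair_index(10)
  homo <- atlas$homotopic_pair[idx[, 1]] == idx[, 2]
  expect_true(all(perm$X[homo, ] == 0.7))
})

test_that("pooling and residuals produce the documented column layouts", {
  nf <- 10
  subj <- paste0("S", 1:21)
  mk <- function(seed) {
    set.seed(seed)
    m <- matrix(rnorm(nf * 21), nf, 21); colnames(m) <- subj; m
  }
  sims <- setNames(lapply(1:7, mk), paste0("m", 1:7))
  pooled7 <- pool_datasets(sims)
  expect_equal(ncol(pooled7$X), 147)
  pooled8 <- pool_datasets(c(list(empirical = mk(99)), sims))
  expect_equal(ncol(pooled8$X), 168)
  # columns grouped by subject, source order preserved within subject
  expect_equal(pooled8$subject[1:8], rep("S1", 8))
  expect_equal(pooled8$source[1:8], c("empirical", paste0("m", 1:7)))
  expect_error(pool_datasets(list(a = mk(1), b = mk(2)[1:5, ])), "feature")
  res <- residual_fc(mk(99), sims)
  expect_equal(ncol(res$X), 147)
  expect_equal(res$X[, 1], mk(99)[, 1] - sims$m1[, 1])
  zero <- residual_fc(sims$m1, list(m1 = sims$m1))
  expect_true(all(zero$X == 0))
})

test_that("BOLD flattening is region-fastest and invertible", {
  r1 <- bold_run(matrix(c(1, 2, 3, 4), 2, 2), tr = 1)  # columns = timepoints
  dm <- bold_to_datamatrix(list(S1 = r1))
  expect_equal(dm$X[, 1], c(1, 2, 3, 4))  # regions at t1, then regions at t2
  back <- unflatten_bold(dm$X[, 1], dm$feature_meta)
  expect_equal(back, r1$values)
  set.seed(12)
  runs <- list(S1 = bold_run(matrix(rnorm(12), 3), tr = 1),
               S2 = bold_run(matrix(rnorm(12), 3), tr = 1))
  dm2 <- bold_to_datamatrix(runs)
  expect_equal(dim(dm2$X), c(12, 2))
  expect_error(bold_to_datamatrix(list(S1 = runs$S1,
                                       S2 = bold_run(matrix(rnorm(8), 2), tr = 1))),
               "same dimensions")
})
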