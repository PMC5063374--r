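make_bold <- function(n_regions = 6, n_samples = 120, seed = 1, tr = 3.29) {
  set.seed(seed)
  bold_run(matrix(rnorm(n_regions * n_samples), n_regions), tr = tr)
}

test_that("global signal regression is an idempotent projection", {
  b <- make_bold()
  g1 <- global_signal_regression(b)
  # after one pass the global mean is exactly zero, so the second pass warns
  # that it degenerates to an intercept-only regression -- and changes nothing
  expect_warning(g2 <- global_signal_regression(g1), "constant")
  expect_true(g1$gsr_applied)
  expect_equal(g1$values, g2$values, tolerance = 1e-10)
  # residuals orthogonal to the original global mean
  gm <- colMeans(b$values)
  r <- apply(g1$values, 1, function(y) abs(cor(y, gm)))
  expect_true(all(r < 1e-10))
  # identical series across regions leave nothing
  same <- bold_run(matrix(rep(rnorm(50), each = 4), 4), tr = 1)
  expect_lt(max(abs(global_signal_regression(same)$values)), 1e-12)
})

test_that("Pearson FC honours affine relations and rejects flat regions", {
  x <- rnorm(80)
  b <- bold_run(rbind(x, 2 * x + 3, -x), tr = 1)
  fc <- pearson_fc(b)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_true(all(diag(fc) == 1))
  expect_true(all(abs(fc) <= 1 + 1e-12))
  flat <- bold_run(rbind(x, rep(1, 80)), tr = 1)
  expect_error(pearson_fc(flat), "zero-variance")
  dropped <- pearson_fc(flat, drop_zero_variance = TRUE)
  expect_equal(dim(dropped), c(1, 1))
  expect_equal(unname(attr(dropped, "dropped")), 2L)
})

test_that("vectorization is lexicographic, subsettable and invertible", {
  atlas <- generate_atlas(6)
  m <- matrix(0, 6, 6)
  m[upper.tri(m)] <- seq_len(15)
  m <- m + t(m)
  v <- vectorize_upper(m, atlas)
  idx <- attr(v, "index")
  expect_equal(idx[1:6, "i"], c(1L, 1L, 1L, 1L, 1L, 2L))  # (1,2)..(1,6),(2,3)
  expect_equal(as.numeric(v), m[idx])
  back <- unvectorize(v)
  expect_equal(back, m)
  intra <- vectorize_upper(m, atlas, subset = "intrahemispheric")
  expect_equal(length(intra), 2 * choose(3, 2))
  h <- atlas$hemisphere
  ii <- attr(intra, "index")
  expect_true(all(h[ii[, 1]] == h[ii[, 2]]))
})

test_that("Gaussian mutual information matches quadrature of the density integral", {
  expect_equal(gaussian_mi(0), 0)
  expect_equal(gaussian_mi(-0.6), gaussian_mi(0.6))
  expect_error(gaussian_mi(1), "< 1")
  # quadrature oracle: rotate to principal axes (u, v) where the joint
  # density factorizes, then integrate the MI integrand on a fine grid
  rho <- 0.9
  h <- 0.01
  g <- seq(-8, 8, by = h)
  u <- matrix(g, length(g), length(g))
  v <- t(u)
  pj <- dnorm(u, sd = sqrt(1 + rho)) * dnorm(v, sd = sqrt(1 - rho))
  x <- (u + v) / sqrt(2); y <- (u - v) / sqrt(2)
  val <- pj * (log(pj) - log(dnorm(x)) - log(dnorm(y)))
  val[pj < 1e-300] <- 0
  quad <- sum(val) * h^2
  expect_equal(gaussian_mi(rho), quad, tolerance = 1e-4)
})

test_that("Gaussian 3-way total correlation equals the log-determinant form", {
  expect_equal(gaussian_ct3(0, 0, 0), 0)
  expect_equal(gaussian_ct3(0.7, 0, 0), gaussian_mi(0.7))
  set.seed(3)
  for (i in 1:20) {
    R <- cor(matrix(rnorm(40 * 3), 40, 3))
    expect_equal(gaussian_ct3(R[1, 2], R[2, 3], R[1, 3]),
                 -0.5 * log(det(R)), tolerance = 1e-12)
  }
  expect_error(gaussian_ct3(0.9, 0.9, -0.9), "positive definite")
})

test_that("kNN mutual information behaves like an information estimate", {
  p0 <- gaussian_pair(2000, 0, seed = 10)
  expect_lt(abs(knn_mutual_information(p0$x, p0$y)), 0.05)
  p9 <- gaussian_pair(5000, 0.9, seed = 11)
  expect_lt(abs(knn_mutual_information(p9$x, p9$y) - gaussian_mi(0.9)), 0.1)
  # degenerate dependence: large and growing with n
  set.seed(12)
  x1 <- rnorm(500); x2 <- rnorm(2000)
  m1 <- knn_mutual_information(x1, x1)
  m2 <- knn_mutual_information(x2, x2)
  expect_gt(m1, 2)
  expect_gt(m2, m1)
  expect_error(knn_mutual_information(x1, x1, k = 500), "k")
})

test_that("pairwise and triplet kNN measures respect the canonical contracts", {
  b <- make_bold(5, 150, seed = 13)
  m <- mi_fc(b)
  expect_equal(length(m), choose(5, 2))
  # an identical sample reordering applied to all regions changes nothing
  perm <- sample(150)
  bp <- bold_run(b$values[, perm], tr = b$tr)
  expect_equal(as.numeric(mi_fc(bp)), as.numeric(m), tolerance = 1e-12)
  tc <- ct3(b)
  expect_equal(length(tc), choose(5, 3))
  # mutually independent series: total correlation near zero
  expect_lt(median(abs(as.numeric(tc))), 0.1)
  expect_error(ct3(make_bold(40, 20), max_triplets = 100), "allow_large")
})

test_that("Gaussian-driven mFC tracks the closed-form image of cFC", {
  set.seed(14)
  n <- 8; Tn <- 800
  A <- matrix(rnorm(n * n, 0, 0.4), n, n); diag(A) <- 1
  X <- t(chol(crossprod(A) / n + diag(n) * 0.5)) %*% matrix(rnorm(n * Tn), n)
  b <- bold_run(X, tr = 1)
  rho <- as.numeric(vectorize_upper(pearson_fc(b)))
  mi <- as.numeric(mi_fc(b))
  expect_lt(median(abs(mi - gaussian_mi(rho))), 0.1)
})

test_that("dynamic FC concatenates per-window patterns in temporal order", {
  b <- make_bold(6, 200, seed = 15)
  d8 <- dynamic_fc(b, 8)
  expect_equal(attr(d8, "n_windows"), 25)
  expect_equal(length(d8), 25 * choose(6, 2))
  # single window reduces to static FC
  dall <- dynamic_fc(b, 200)
  expect_equal(as.numeric(dall), as.numeric(vectorize_upper(pearson_fc(b))))
  # first block equals FC of the first window
  fc1 <- pearson_fc(bold_run(b$values[, 1:8], tr = b$tr))
  expect_equal(d8[1:15], as.numeric(vectorize_upper(fc1)))
  expect_error(dynamic_fc(b, 7), "divide")
  expect_equal(attr(dynamic_fc(b, 7, truncate = TRUE), "n_windows"), 28)
  # window-averaged FC correlates with full-run FC on stationary data
  wm <- rowMeans(matrix(as.numeric(d8), ncol = 25))
  expect_gt(cor(wm, as.numeric(dall)), 0.8)
})
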