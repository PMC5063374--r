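test_that("generated SC matrices satisfy the type invariants over random draws", {
  set.seed(1)
  for (i in 1:100) {
    n <- sample(c(6L, 8L, 10L), 1)
    atlas <- generate_atlas(n)
    gt <- generate_ground_truth_sc(
      atlas, density_intra = runif(1, 0.5, 1), density_inter = runif(1, 0, 0.5),
      homotopic_weight = sample(c(0, 0.5), 1), weight_log_sd = runif(1, 0.3, 1.5),
      seed = i)
    spec <- cohort_spec(3, gain_sd = 0.3, noise_sd = 0.002, seed = i)
    sub <- generate_subject_sc(gt, spec, 1)
    for (sc in list(gt, sub)) {
      w <- sc$weights
      expect_identical(w, t(w))
      expect_true(all(diag(w) == 0))
      expect_true(all(w >= 0))
      nz <- w[w > 0]
      if (sc$threshold_applied > 0 && length(nz)) {
        expect_gte(min(nz), sc$threshold_applied)
      }
    }
  }
})

test_that("ground-truth construction honours density, homotopy and degenerate limits", {
  atlas <- generate_atlas(20)
  # no cross-hemisphere links at all -> block-diagonal
  gt0 <- generate_ground_truth_sc(atlas, density_inter = 0, homotopic_weight = 0,
                                  seed = 3)
  inter <- scfc:::interhemispheric_mask(atlas)
  expect_true(all(gt0$weights[inter] == 0))
  # homotopic entries planted exactly
  gt5 <- generate_ground_truth_sc(atlas, homotopic_weight = 0.5, seed = 3)
  homo <- scfc:::homotopic_mask(atlas)
  expect_true(all(gt5$weights[homo] == 0.5))
  expect_equal(sum(homo), 20)
  # complete equal-weight graph in the degenerate limit
  gtc <- generate_ground_truth_sc(atlas, density_intra = 1, density_inter = 0,
                                  homotopic_weight = 0, weight_log_sd = 1e-9,
                                  seed = 3)
  intra <- !inter; diag(intra) <- FALSE
  expect_true(all(gtc$weights[intra] > 0))
  expect_lt(diff(range(gtc$weights[intra])), 1e-6)
  expect_error(generate_ground_truth_sc(atlas, density_intra = 1.2), "probabilities")
})

test_that("subject SC is the gain-scaled core in the noise-free limit", {
  gt <- tiny_sc(10, seed = 4)
  spec0 <- cohort_spec(3, gain_sd = 1e-12, noise_sd = 1e-12, seed = 5)
  sub <- generate_subject_sc(gt, spec0, 1)
  supra <- gt$weights >= 0.001
  expect_equal(sub$weights[supra], gt$weights[supra], tolerance = 1e-6)
  # pure multiplicative model: all nonzero entries scale by the same factor
  specg <- cohort_spec(3, gain_sd = 0.5, noise_sd = 1e-12, seed = 6)
  subg <- generate_subject_sc(gt, specg, 2)
  g <- attr(subg, "gain")
  keep <- subg$weights > 0 & gt$weights > 0
  ratios <- subg$weights[keep] / gt$weights[keep]
  expect_lt(diff(range(ratios)), 1e-8)
  expect_equal(ratios[1], g, tolerance = 1e-8)
})

test_that("a multiplicative-gain cohort is essentially one linear dimension", {
  atlas <- generate_atlas(40)
  gt <- generate_ground_truth_sc(atlas, seed = 7)
  spec <- cohort_spec(21, gain_sd = 0.2, noise_sd = 0.0005, seed = 8)
  X <- vapply(1:21, function(s) {
    as.numeric(vectorize_upper(generate_subject_sc(gt, spec, s)$weights, atlas))
  }, numeric(choose(40, 2)))
  f <- svd_variance(X)$variance_fractions
  expect_gt(f[1], 0.95)
  # noise-free rank-1 cohort: first fraction is exactly 1
  X0 <- outer(as.numeric(vectorize_upper(gt$weights, atlas)), exp(rnorm(5)))
  expect_equal(svd_variance(X0)$variance_fractions[1], 1, tolerance = 1e-12)
})

test_that("interhemispheric degradation only removes cross-hemisphere pairs", {
  gt <- tiny_sc(20, seed = 9)
  same <- degrade_sc(gt, 0, seed = 1)
  expect_equal(same$weights, gt$weights)
  gone <- degrade_sc(gt, 1, seed = 1)
  inter <- scfc:::interhemispheric_mask(gt$atlas)
  expect_true(all(gone$weights[inter] == 0))
  expect_equal(gone$weights[!inter], gt$weights[!inter])
  # survival count falls in the binomial 99% interval
  atlas <- generate_atlas(30)
  dense <- generate_ground_truth_sc(atlas, density_intra = 0.5,
                                    density_inter = 0.9, homotopic_weight = 0.5,
                                    seed = 10)
  up <- upper.tri(dense$weights) & scfc:::interhemispheric_mask(atlas)
  n_pairs <- sum(dense$weights[up] > 0)
  half <- degrade_sc(dense, 0.5, seed = 11)
  surv <- sum(half$weights[up] > 0)
  bounds <- qbinom(c(0.005, 0.995), n_pairs, 0.5)
  expect_gte(surv, bounds[1])
  expect_lte(surv, bounds[2])
})

test_that("planted low-rank datasets honour rank and fraction contracts", {
  d0 <- planted_lowrank_dataset(50, 8, 1, 1, noise_sd = 0, seed = 1)
  sv <- svd(d0$X)$d
  expect_gt(sv[1], 0)
  expect_lt(sv[2] / sv[1], 1e-12)
  expect_error(planted_lowrank_dataset(50, 8, 2, c(0.8, 0.4), 0.1), "sum")
  expect_error(planted_lowrank_dataset(50, 8, 1, 0.5, noise_sd = 0), "sum to 1")
  # realized leading fraction tracks the request under noise
  d2 <- planted_lowrank_dataset(300, 15, 2, c(0.55, 0.25), 0.2, seed = 2)
  f <- svd_variance(d2$X)$variance_fractions
  expect_lt(abs(f[1] - 0.55), 0.05)
  expect_lt(abs(f[2] - 0.25), 0.05)
})

test_that("identical master seeds reproduce the cohort exactly", {
  a <- generate_ground_truth_sc(generate_atlas(12), seed = 42)
  b <- generate_ground_truth_sc(generate_atlas(12), seed = 42)
  expect_identical(a$weights, b$weights)
  spec <- cohort_spec(4, seed = 42)
  expect_identical(generate_subject_sc(a, spec, 2)$weights,
                   generate_subject_sc(b, spec, 2)$weights)
})
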