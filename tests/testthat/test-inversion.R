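test_that("the log transform is anchored at its reference constant", {
  tr <- transform_sc(c(1e-4, 1e-4 * exp(1), 1e-7, 0.05))
  expect_equal(tr$mask, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(tr$sc_prime[1:2], c(0, 1))
  expect_error(transform_sc(1, floor = 0), "floor")
  # transform and exponentiation invert up to the ratio of reference constants
  x <- c(0.002, 0.03, 0.7)
  sc_p <- transform_sc(x, ref = 1e-4)$sc_prime
  expect_equal(1e-3 * exp(sc_p), x * (1e-3 / 1e-4), tolerance = 1e-12)
})

test_that("polynomial fitting recovers exact quartics and degenerate orders", {
  set.seed(1)
  x <- sort(runif(200, -2, 4))
  co <- c(0.2, 0.5, -0.03, 0.004, 0.001)
  y <- drop(outer(x, 0:4, `^`) %*% co)
  map <- fit_sc_fc_map(x, y)
  expect_equal(map$coefficients, co, tolerance = 1e-8)
  expect_equal(map$fit_domain, range(x))
  m0 <- fit_sc_fc_map(x, y, order = 0)
  expect_equal(m0$coefficients, mean(y))
  expect_error(fit_sc_fc_map(x[1:3], y[1:3], order = 4), "order \\+ 1")
  expect_error(fit_sc_fc_map(x, y[1:10]), "matched")
})

test_that("numerical inversion round-trips on the monotone branch and clamps outside", {
  set.seed(2)
  x <- sort(runif(300, 0, 5))
  y <- 0.1 + 0.25 * x + 0.01 * x^2 + 0.001 * x^3 + 1e-4 * x^4  # monotone up
  map <- fit_sc_fc_map(x, y)
  est <- invert_fc(predict_map(map, x), map, ref_out = 1e-4)
  expect_lt(max(abs(attr(est, "sc_prime") - x)), 1e-8)
  expect_false(any(attr(est, "clamped")))
  # monotone map: estimated SC ordering matches FC ordering
  expect_false(is.unsorted(as.numeric(est)))
  # FC below the range is clamped to the boundary and flagged
  lowest <- invert_fc(min(y) - 1, map)
  expect_true(attr(lowest, "clamped"))
  expect_equal(attr(lowest, "sc_prime"), map$fit_domain[1], tolerance = 1e-6)
})

test_that("a polynomial with interior turning points triggers the branch error", {
  map <- structure(list(coefficients = c(0, -3, 0, 1, 0), order = 4,
                        fit_domain = c(-2, 2), mass_quantiles = c(-1.8, 1.8),
                        residual_sd = 0, n_points = 100),
                   class = "polynomial_map")
  expect_error(invert_fc(0.5, map), "monotone branch")
})

test_that("inversion agrees with a brute-force dense-grid argmin oracle", {
  set.seed(3)
  x <- sort(runif(200, 0, 3))
  y <- 0.05 + 0.4 * x + 0.02 * x^2 + 0.002 * x^3 + 2e-4 * x^4
  map <- fit_sc_fc_map(x, y)
  targets <- seq(min(y) + 0.01, max(y) - 0.01, length.out = 25)
  est <- attr(invert_fc(targets, map), "sc_prime")
  grid <- seq(map$fit_domain[1], map$fit_domain[2], length.out = 2e6)
  py <- predict_map(map, grid)
  oracle <- vapply(targets, function(tt) grid[which.min(abs(py - tt))], numeric(1))
  expect_lt(max(abs(est - oracle)), 1e-5)  # grid resolution bound
})

test_that("the full estimation pipeline rejects an empty empirical set", {
  atlas <- generate_atlas(8)
  gt <- generate_ground_truth_sc(atlas, seed = 4)
  cohort <- list(S1 = gt, S2 = gt, S3 = gt)
  expect_error(estimate_sc_pipeline(matrix(numeric(0), 28, 0), list(), cohort),
               "empty")
})
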