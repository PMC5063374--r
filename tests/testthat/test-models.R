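test_that("SAR analytic FC matches Monte-Carlo sampling of the recursion", {
  sc <- tiny_sc(6, seed = 2)
  fc0 <- sar_fc(sc, 0)
  expect_equal(fc0, diag(6), ignore_attr = TRUE)
  fc <- sar_fc(sc, 0.5)
  expect_equal(fc, t(fc))
  expect_true(all(diag(fc) == 1))
  expect_true(all(abs(fc) <= 1))
  set.seed(20)
  A <- solve(diag(6) - 0.5 * scfc:::row_normalize(sc$weights))
  X <- A %*% matrix(rnorm(6 * 2e5), 6)
  expect_lt(max(abs(fc - cor(t(X)))), 0.02)
  expect_error(sar_fc(sc, 1.5), "spectral radius")
})

test_that("simulated dynamics are deterministic in (seed, config) and shaped correctly", {
  sc <- tiny_sc(6)
  for (model in c("rate", "kuramoto", "wilson_cowan", "fitzhugh_nagumo")) {
    cfg <- model_config(model, duration = 12, burn_in = 2, seed = 31)
    a <- simulate_dynamics(sc, cfg)
    b <- simulate_dynamics(sc, cfg)
    expect_identical(a$values, b$values)
    expect_true(all(is.finite(a$values)))
    expect_equal(dim(a$values), c(6, floor((12 - 2) / cfg$dt_sample)))
  }
  expect_error(model_config("unknown_model"), "arg")
  expect_error(simulate_dynamics(sc, model_config("sar")), "sar_fc")
})

test_that("uncoupled Kuramoto oscillators advance at their natural frequency", {
  sc <- tiny_sc(6)
  cfg <- model_config("kuramoto", global_coupling = 0, noise_sd = 0,
                      duration = 30, burn_in = 5,
                      model_params = list(f0 = 1, f_sd = 0), seed = 5)
  nts <- simulate_dynamics(sc, cfg)
  # every observable is a pure 1 Hz sinusoid: locate the spectral peak
  for (i in 1:6) {
    x <- nts$values[i, ]
    sp <- Mod(fft(x - mean(x)))[2:(length(x) / 2)]
    f_axis <- (seq_along(sp)) / (length(x) * cfg$dt_sample)
    expect_equal(f_axis[which.max(sp)], 1, tolerance = 0.05)
  }
})

test_that("uncoupled rate units are asymptotically uncorrelated", {
  sc <- tiny_sc(6)
  cfg <- model_config("rate", global_coupling = 0, duration = 310, burn_in = 10,
                      dt_sample = 0.1, seed = 6)
  nts <- simulate_dynamics(sc, cfg)
  r <- cor(t(nts$values))
  off <- abs(r[upper.tri(r)])
  expect_lt(mean(off), 0.05)
  expect_lt(max(off), 0.15)
})

test_that("coupling increases functional coupling in every model regime", {
  sc <- tiny_sc(10, seed = 3)
  mean_abs_fc <- function(model, G) {
    cfg <- model_config(model, global_coupling = G, duration = 40, burn_in = 10,
                        seed = 7)
    if (model == "sar") {
      fc <- sar_fc(sc, G)
    } else {
      nts <- simulate_dynamics(sc, cfg)
      fc <- cor(t(nts$values))
    }
    mean(abs(fc[upper.tri(fc)]))
  }
  # G_max per model sits in the responsive regime below saturation: strong
  # coupling saturates the Wilson-Cowan sigmoid and quenches FitzHugh-Nagumo
  # oscillations, so the monotone trend is asserted from 0 into that regime
  for (model in model_names()) {
    gmax <- switch(model, sar = 0.9, rate = 0.9, kuramoto = 3,
                   wilson_cowan = 1, fitzhugh_nagumo = 0.25)
    expect_gt(mean_abs_fc(model, gmax), mean_abs_fc(model, 0))
  }
})

test_that("coupling grid search maximizes target correlation with smallest-tie rule", {
  sc <- tiny_sc(8, seed = 8)
  target <- vectorize_upper(sar_fc(sc, 0.4), sc$atlas)
  cfg <- model_config("sar", seed = 9)
  g <- tune_global_coupling("sar", sc, target, grid = c(0.1, 0.4, 0.7), cfg)
  expect_equal(as.numeric(g), 0.4)
  ev <- attr(g, "evaluations")
  expect_equal(nrow(ev), 3)
  expect_equal(which.max(ev$correlation), 2L)
  # single-element grid returns that element
  expect_equal(as.numeric(tune_global_coupling("sar", sc, target, 0.25, cfg)), 0.25)
  # duplicated optimum -> smallest returned
  gd <- tune_global_coupling("sar", sc, target, c(0.4, 0.4), cfg)
  expect_equal(as.numeric(gd), 0.4)
  expect_error(tune_global_coupling("sar", sc, target, numeric(0)), "empty")
  expect_error(tune_global_coupling("sar", sc, target, c(2, 3)), "stable")
})

test_that("simulated FC vector obeys the pair-count and seeding contracts", {
  sc <- tiny_sc(8, seed = 10)
  cfg <- model_config("rate", seed = 11)
  v1 <- simulate_fc("rate", sc, cfg, n_samples = 30)
  v2 <- simulate_fc("rate", sc, cfg, n_samples = 30)
  expect_identical(as.numeric(v1), as.numeric(v2))
  expect_equal(length(v1), choose(8, 2))
  # G = 0 with GSR: entries concentrate near the mean-regression baseline
  cfg0 <- model_config("rate", global_coupling = 0, seed = 12)
  v0 <- simulate_fc("rate", sc, cfg0, n_samples = 150)
  expect_equal(median(as.numeric(v0)), -1 / (8 - 1), tolerance = 0.08)
})
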