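#' Supported generative models
#' @return Character vector of model names.
#' @export
model_names <- function() c("sar", "rate", "wilson_cowan", "kuramoto",
                            "fitzhugh_nagumo")

#' Default regime-specific constants of a generative model
#'
#' The package adopts standard textbook formulations of each regime (the
#' coupling through the SC matrix and the hemodynamic read-out are what the
#' pipeline studies, not the particular parameterizations):
#' \describe{
#'   \item{rate}{linear rate model `tau dx = (-x + G W x) dt + tau sigma dW`
#'     with `tau` (s).}
#'   \item{kuramoto}{phase oscillators with natural frequencies drawn once
#'     per run from `N(2 pi f0, (2 pi f_sd)^2)`; `f0`, `f_sd` in Hz.}
#'   \item{wilson_cowan}{one excitatory/inhibitory pair per region with
#'     sigmoidal gain; constants `c1..c4`, gains/thresholds `a_e, th_e, a_i,
#'     th_i`, drives `P`, `Q`, time constant `tau` (s). Coupling enters the
#'     excitatory input.}
#'   \item{fitzhugh_nagumo}{fast-slow pair `v, w` with cubic fast nullcline;
#'     `a`, `b`, `phi`, external drive `I_ext`, and `tau` (s), the duration
#'     of one model time unit.}
#' }
#' @param model_name One of [model_names()] (not `"sar"`, which is analytic).
#' @return Named list of constants.
#' @export
default_model_params <- function(model_name) {
  switch(model_name,
    rate = list(tau = 0.1),
    kuramoto = list(f0 = 1, f_sd = 0.1),
    wilson_cowan = list(c1 = 16, c2 = 12, c3 = 15, c4 = 3, a_e = 1.3,
                        th_e = 4, a_i = 2, th_i = 3.7, P = 1.25, Q = 0,
                        tau = 0.01),
    fitzhugh_nagumo = list(a = 0.7, b = 0.8, phi = 0.08, I_ext = 0.4,
                           tau = 0.02),
    stop("unknown model: ", model_name, call. = FALSE)
  )
}

default_coupling <- function(model_name) {
  switch(model_name, sar = 0.6, rate = 0.7, kuramoto = 1.5,
         wilson_cowan = 1, fitzhugh_nagumo = 0.3)
}

default_noise_sd <- function(model_name) {
  switch(model_name, sar = 1, rate = 1, kuramoto = 0.5, wilson_cowan = 0.05,
         fitzhugh_nagumo = 0.3)
}

#' Configure a dynamical simulation
#'
#' @param model_name One of [model_names()].
#' @param global_coupling Nonnegative scalar `G` multiplying the
#'   row-normalized SC in the coupling term; defaults to a model-specific
#'   value in the weakly-coupled regime.
#' @param noise_sd Diffusion amplitude of the Euler-Maruyama noise.
#' @param dt Integration step in seconds (default 0.001).
#' @param duration Simulated time in seconds (after `burn_in` the observable
#'   is kept).
#' @param burn_in Initial transient discarded, in seconds (default 10).
#' @param dt_sample Sampling interval of the stored observable in seconds
#'   (default 0.01); must be a multiple of `dt`.
#' @param model_params Overrides merged into [default_model_params()].
#' @param seed Integer seed; identical `(seed, config)` give identical
#'   trajectories.
#' @return An object of class `model_config`.
#' @export
model_config <- function(model_name, global_coupling = NULL, noise_sd = NULL,
                         dt = 0.001, duration = 60, burn_in = 10,
                         dt_sample = 0.01, model_params = list(), seed = 1) {
  model_name <- match.arg(model_name, model_names())
  if (duration <= burn_in) stop("duration must exceed burn_in", call. = FALSE)
  if (dt <= 0 || dt_sample < dt) stop("need 0 < dt <= dt_sample", call. = FALSE)
  if (abs(dt_sample / dt - round(dt_sample / dt)) > 1e-8) {
    stop("dt_sample must be a multiple of dt", call. = FALSE)
  }
  params <- if (model_name == "sar") list() else default_model_params(model_name)
  params[names(model_params)] <- model_params
  structure(list(
    model_name = model_name,
    global_coupling = if (is.null(global_coupling)) default_coupling(model_name) else global_coupling,
    noise_sd = if (is.null(noise_sd)) default_noise_sd(model_name) else noise_sd,
    dt = dt, duration = duration, burn_in = burn_in, dt_sample = dt_sample,
    model_params = params, seed = as.integer(seed)
  ), class = "model_config")
}

# row-normalize SC so that the stability/coupling scale is G-controlled
# regardless of the SC's overall magnitude; zero rows stay zero
row_normalize <- function(w) {
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  w / rs
}

#' Analytic functional connectivity of the SAR model
#'
#' In the spatial autoregressive model `x = G W x + e` (with `W` the
#' row-normalized SC and i.i.d. innovations `e`), the covariance has the
#' closed form `Sigma = sigma^2 (I - G W)^{-1} (I - G W)^{-t}`; the simulated
#' FC is this covariance converted to correlation, with no time-series
#' simulation involved.
#'
#' @param sc An `sc_matrix`.
#' @param coupling Nonnegative scalar `G`; the spectral radius of `G W` must
#'   be below 1.
#' @param noise_sd Innovation SD (does not affect the correlation).
#' @return Correlation matrix (symmetric, unit diagonal).
#' @export
sar_fc <- function(sc, coupling, noise_sd = 1) {
  stopifnot(inherits(sc, "sc_matrix"))
  if (coupling < 0) stop("coupling must be >= 0", call. = FALSE)
  W <- row_normalize(sc$weights)
  n <- nrow(W)
  rho <- max(abs(eigen(coupling * W, only.values = TRUE)$values))
  if (rho >= 1) {
    stop(sprintf("SAR unstable: spectral radius of G*W is %.3f >= 1", rho),
         call. = FALSE)
  }
  A <- solve(diag(n) - coupling * W)
  sig <- noise_sd^2 * tcrossprod(A)
  fc <- stats::cov2cor(sig)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' Simulate regional neural activity on an SC backbone
#'
#' Integrates the configured model by Euler-Maruyama at step `dt`, coupled
#' through `G` times the row-normalized SC, discards the burn-in, and stores
#' the model observable (rate, excitatory activity, `sin(phase)` for
#' Kuramoto, the fast variable for FitzHugh-Nagumo) every `dt_sample`
#' seconds. Identical `(seed, config)` give identical output; non-finite
#' states raise a divergence error naming the blow-up time.
#'
#' @param sc An `sc_matrix`.
#' @param config A [model_config()] (any model except `"sar"`, whose FC is
#'   analytic, see [sar_fc()]).
#' @return An object of class `neural_time_series` with `values` (regions x
#'   samples) and `dt_sample`.
#' @export
simulate_dynamics <- function(sc, config) {
  stopifnot(inherits(sc, "sc_matrix"), inherits(config, "model_config"))
  if (config$model_name == "sar") {
    stop("the SAR model has no time-domain simulation; use sar_fc()",
         call. = FALSE)
  }
  W <- row_normalize(sc$weights)
  C <- config$global_coupling * W
  n <- nrow(C)
  sample_every <- as.integer(round(config$dt_sample / config$dt))
  n_samples <- as.integer(floor((config$duration - config$burn_in) / config$dt_sample))
  burn_steps <- as.integer(round(config$burn_in / config$dt))
  p <- config$model_params
  vals <- with_substream(config$seed, "dynamics", config$model_name, expr = {
    switch(config$model_name,
      rate = .sim_rate_cpp(C, p$tau, config$noise_sd, config$dt, burn_steps,
                           n_samples, sample_every),
      kuramoto = {
        omega <- rnorm(n, 2 * pi * p$f0, 2 * pi * p$f_sd)
        .sim_kuramoto_cpp(C, omega, config$noise_sd, config$dt, burn_steps,
                          n_samples, sample_every)
      },
      wilson_cowan = .sim_wilson_cowan_cpp(
        C, unlist(p[c("c1", "c2", "c3", "c4", "a_e", "th_e", "a_i", "th_i",
                      "P", "Q", "tau")]),
        config$noise_sd, config$dt, burn_steps, n_samples, sample_every),
      fitzhugh_nagumo = .sim_fhn_cpp(
        C, unlist(p[c("a", "b", "phi", "I_ext", "tau")]),
        config$noise_sd, config$dt, burn_steps, n_samples, sample_every)
    )
  })
  rownames(vals) <- sc$atlas$region
  structure(list(values = vals, dt_sample = config$dt_sample),
            class = "neural_time_series")
}

#' @export
print.neural_time_series <- function(x, ...) {
  cat(sprintf("neural_time_series: %d regions x %d samples at %g s\n",
              nrow(x$values), ncol(x$values), x$dt_sample))
  invisible(x)
}
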