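#' Balloon-Windkessel hemodynamic constants
#'
#' The widely used defaults of the model's source formulation: signal decay
#' `kappa` (1/s), flow feedback `gamma` (1/s), venous transit time `tau` (s),
#' vessel stiffness exponent `alpha`, resting oxygen extraction `E0` and
#' resting venous volume fraction `V0`.
#'
#' @param kappa,gamma,tau,alpha,E0,V0 Positive reals; `alpha` in `(0, 1]`,
#'   `E0` in `(0, 1)`.
#' @return A named list of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                               alpha = 0.32, E0 = 0.34, V0 = 0.02) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (E0 <= 0 || E0 >= 1) stop("E0 must be in (0, 1)", call. = FALSE)
  if (any(c(kappa, gamma, tau, V0) <= 0)) {
    stop("hemodynamic constants must be positive", call. = FALSE)
  }
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 E0 = E0, V0 = V0), class = "hemodynamic_params")
}

#' Balloon-Windkessel hemodynamic forward model
#'
#' Converts regional neural activity into BOLD percent signal change through
#' the standard 4-state hemodynamic system per region (vasodilatory signal,
#' inflow, venous volume, deoxyhemoglobin), integrated by Euler on the neural
#' sampling grid and read out every `tr` seconds. Doubling `tr` therefore
#' returns every other sample of the finer-`tr` run (same integration grid).
#'
#' @param neural A `neural_time_series`.
#' @param params [hemodynamic_params()].
#' @param tr BOLD sampling interval in seconds (default 3.29); must be at
#'   least `dt_sample` and an integer multiple of it.
#' @param max_step Upper bound on the internal Euler step in seconds (default
#'   0.005); coarser neural grids are substepped down to it, with the neural
#'   drive held constant within each neural sample.
#' @return A `bold_run` (`gsr_applied = FALSE`).
#' @export
balloon_windkessel <- function(neural, params = hemodynamic_params(),
                               tr = 3.29, max_step = 0.005) {
  stopifnot(inherits(neural, "neural_time_series"))
  if (tr < neural$dt_sample) stop("tr must be >= dt_sample", call. = FALSE)
  step <- tr / neural$dt_sample
  if (abs(step - round(step)) > 1e-8) {
    stop("tr must be an integer multiple of dt_sample", call. = FALSE)
  }
  step <- as.integer(round(step))
  substeps <- max(1L, as.integer(ceiling(neural$dt_sample / max_step)))
  bold <- .balloon_windkessel_cpp(neural$values, neural$dt_sample,
                                  unlist(params), substeps)
  keep <- seq(step, ncol(bold), by = step)
  bold_run(bold[, keep, drop = FALSE], tr = tr, gsr_applied = FALSE)
}
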