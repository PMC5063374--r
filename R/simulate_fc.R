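#' Simulate a BOLD run from an SC matrix
#'
#' Full forward chain for the time-domain models: neural dynamics on the SC
#' backbone, Balloon-Windkessel hemodynamics, and sampling at `tr`. Beyond
#' the neural burn-in, the first `hemo_settle` BOLD volumes are discarded so
#' that the hemodynamic states have reached their stationary regime; the
#' simulation duration is extended accordingly, so the run always has exactly
#' `n_samples` volumes.
#'
#' @param sc An `sc_matrix`.
#' @param config A [model_config()] (its `duration` is overridden by
#'   `n_samples`).
#' @param n_samples Number of BOLD volumes to produce (default 200).
#' @param tr Sampling interval in seconds (default 3.29).
#' @param hemo_settle Number of initial BOLD volumes discarded (default 6).
#' @param hemo_params [hemodynamic_params()].
#' @return A `bold_run` of `n_samples` volumes.
#' @export
simulate_bold <- function(sc, config, n_samples = 200, tr = 3.29,
                          hemo_settle = 6, hemo_params = hemodynamic_params()) {
  total <- n_samples + hemo_settle
  config$duration <- config$burn_in + total * tr
  neural <- simulate_dynamics(sc, config)
  bold <- balloon_windkessel(neural, params = hemo_params, tr = tr)
  keep <- (hemo_settle + 1):ncol(bold$values)
  keep <- utils::tail(keep, n_samples)
  bold_run(bold$values[, keep, drop = FALSE], tr = tr, gsr_applied = FALSE)
}

#' Simulated functional connectivity under a generative model
#'
#' For the time-domain models: simulate BOLD, regress out the global signal,
#' compute Pearson FC, and vectorize canonically. For the SAR model the FC is
#' computed analytically from the model covariance ([sar_fc()]) with no
#' time-series simulation and no GSR.
#'
#' @param model_name One of [model_names()].
#' @param sc An `sc_matrix`.
#' @param config A [model_config()] for `model_name` (built with defaults if
#'   `NULL`).
#' @param n_samples,tr BOLD run geometry (defaults 200 volumes at 3.29 s).
#' @param gsr Apply global signal regression before FC (default `TRUE`;
#'   ignored for SAR, which is analytic).
#' @param seed Seed used when `config` is `NULL`.
#' @return A `connectivity_vector` (measure `"cFC"`, length `choose(n, 2)`).
#' @export
simulate_fc <- function(model_name, sc, config = NULL, n_samples = 200,
                        tr = 3.29, gsr = TRUE, seed = 1) {
  model_name <- match.arg(model_name, model_names())
  if (is.null(config)) config <- model_config(model_name, seed = seed)
  if (model_name == "sar") {
    fc <- sar_fc(sc, coupling = config$global_coupling,
                 noise_sd = config$noise_sd)
  } else {
    bold <- simulate_bold(sc, config, n_samples = n_samples, tr = tr)
    if (gsr) bold <- global_signal_regression(bold)
    fc <- pearson_fc(bold)
  }
  vectorize_upper(fc, sc$atlas)
}

#' Tune the global coupling against a target FC
#'
#' Evaluates every coupling on the grid (in increasing order), computing the
#' Pearson correlation between the vectorized simulated FC and the target
#' vector, and returns the grid value with the highest correlation; ties go
#' to the smaller coupling. Each grid point is evaluated under its own
#' derived seed so the search is reproducible. For SAR, unstable couplings
#' are skipped (an error is raised only if the whole grid is unstable).
#'
#' @param model_name One of [model_names()].
#' @param sc An `sc_matrix`.
#' @param target_fc_vector Target connectivity vector (same pair order).
#' @param grid Numeric vector of candidate couplings.
#' @param config Base [model_config()] (defaults if `NULL`); its
#'   `global_coupling` is replaced per grid point.
#' @param n_samples,tr Passed to [simulate_fc()].
#' @return The selected coupling, with attribute `"evaluations"`: a data
#'   frame of (coupling, correlation) for the whole grid.
#' @export
tune_global_coupling <- function(model_name, sc, target_fc_vector, grid,
                                 config = NULL, n_samples = 200, tr = 3.29) {
  if (length(grid) == 0) stop("empty coupling grid", call. = FALSE)
  model_name <- match.arg(model_name, model_names())
  if (is.null(config)) config <- model_config(model_name)
  grid <- sort(grid)
  r <- rep(NA_real_, length(grid))
  for (gi in seq_along(grid)) {
    cfg <- config
    cfg$global_coupling <- grid[gi]
    cfg$seed <- substream_seed(config$seed, "tune", gi)
    fc <- tryCatch(
      simulate_fc(model_name, sc, config = cfg, n_samples = n_samples, tr = tr),
      error = function(e) {
        if (grepl("unstable", conditionMessage(e))) NULL else stop(e)
      })
    if (!is.null(fc)) r[gi] <- cor(as.numeric(fc), as.numeric(target_fc_vector))
  }
  if (all(is.na(r))) {
    stop("no stable coupling on the grid (SAR spectral radius >= 1 throughout)",
         call. = FALSE)
  }
  best <- which.max(r)  # first maximum = smallest coupling on ties
  structure(grid[best],
            evaluations = data.frame(coupling = grid, correlation = r))
}
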