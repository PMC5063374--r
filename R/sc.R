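#' Construct a structural-connectivity matrix object
#'
#' Wraps a symmetric nonnegative weight matrix with its atlas into an
#' `sc_matrix` object. Entry `(r, s)` is the structural connectivity index
#' between regions `r` and `s`; the diagonal is zero (no self-connections).
#'
#' @param weights Square numeric matrix, symmetric, nonnegative, zero
#'   diagonal, with as many rows as atlas regions.
#' @param atlas A [generate_atlas()] `region_atlas`.
#' @param threshold_applied Nonnegative scalar: the detection threshold that
#'   has been applied to `weights` (0 if none). Every nonzero entry must be at
#'   least this value.
#' @return An object of class `sc_matrix` with elements `weights`, `atlas`,
#'   `threshold_applied`.
#' @export
sc_matrix <- function(weights, atlas, threshold_applied = 0) {
  validate_atlas(atlas)
  if (!is.matrix(weights) || nrow(weights) != ncol(weights) ||
      nrow(weights) != atlas$n_regions) {
    stop("weights must be a square matrix matching the atlas size", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and nonnegative", call. = FALSE)
  }
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("weights must be symmetric", call. = FALSE)
  }
  if (any(diag(weights) != 0)) {
    stop("diagonal must be zero (no self-connections)", call. = FALSE)
  }
  nz <- weights[weights > 0]
  if (threshold_applied > 0 && length(nz) && min(nz) < threshold_applied) {
    stop("nonzero entries below the applied threshold", call. = FALSE)
  }
  dimnames(weights) <- list(atlas$region, atlas$region)
  structure(list(weights = weights, atlas = atlas,
                 threshold_applied = threshold_applied),
            class = "sc_matrix")
}

#' @export
print.sc_matrix <- function(x, ...) {
  nz <- sum(x$weights > 0) / 2
  cat("sc_matrix:", x$atlas$n_regions, "regions,", nz, "connections",
      sprintf("(threshold %g)\n", x$threshold_applied))
  invisible(x)
}

#' Apply a detection threshold to an SC matrix
#'
#' Entries below `threshold` are set to zero; supra-threshold values are kept
#' as such. The default 0.001 is the conventional floor for
#' tractography-derived connectivity indices.
#'
#' @param sc An `sc_matrix`.
#' @param threshold Nonnegative scalar.
#' @return A thresholded `sc_matrix` with `threshold_applied = threshold`.
#' @export
threshold_sc <- function(sc, threshold = 0.001) {
  w <- sc$weights
  w[w < threshold] <- 0
  sc_matrix(w, sc$atlas, threshold_applied = threshold)
}

#' Describe a synthetic cohort
#'
#' Parameters of the generative model for a multi-subject SC cohort: each
#' subject's SC is a shared ground-truth core scaled by a subject-specific
#' lognormal global gain, plus symmetric Gaussian entry noise, clipped at zero
#' and thresholded. This reproduces the empirical situation where individual
#' connectomes differ essentially by a global multiplicative constant, with a
#' tunable residual.
#'
#' @param n_subjects Number of subjects (default 21).
#' @param gain_sd SD of the log of the per-subject global gain (default 0.2).
#' @param noise_sd SD of the additive entrywise noise (default 0.002, i.e.
#'   one fifth of the default median connection weight).
#' @param interhemispheric_miss_rate Probability that a true interhemispheric
#'   connection goes undetected in the measured (diffusion-style) SC; default
#'   0.8, emulating the systematic under-detection of such connections by
#'   tractography.
#' @param seed Integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 21, gain_sd = 0.2, noise_sd = 0.002,
                        interhemispheric_miss_rate = 0.8, seed = 1) {
  if (gain_sd <= 0 || noise_sd <= 0) stop("sds must be > 0", call. = FALSE)
  if (interhemispheric_miss_rate < 0 || interhemispheric_miss_rate > 1) {
    stop("interhemispheric_miss_rate must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), gain_sd = gain_sd,
                 noise_sd = noise_sd,
                 interhemispheric_miss_rate = interhemispheric_miss_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# connectivity check (BFS) on an adjacency matrix restricted to `idx`
is_connected <- function(w, idx) {
  a <- w[idx, idx, drop = FALSE] > 0
  n <- nrow(a)
  if (n == 0) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(a[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Generate a ground-truth structural connectome
#'
#' Samples the shared core SC of a synthetic cohort: within-hemisphere edges
#' appear with probability `density_intra` and cross-hemisphere (non-homotopic)
#' edges with probability `density_inter`; nonzero weights are lognormal with
#' median `weight_scale` and log-SD `weight_log_sd`; every homotopic pair is
#' set to `homotopic_weight` exactly (0 removes them). Each intra-hemispheric
#' subgraph is resampled until connected so that coupled dynamics do not split
#' into isolated components.
#'
#' @param atlas A `region_atlas`.
#' @param density_intra,density_inter Edge probabilities in `[0, 1]`.
#' @param homotopic_weight Nonnegative weight given to all homotopic pairs.
#' @param weight_log_sd Positive log-scale SD of the nonzero weights.
#' @param weight_scale Median of the nonzero weights (default 0.01, an order
#'   of magnitude above the conventional 0.001 detection threshold).
#' @param seed Integer seed.
#' @return An `sc_matrix` (unthresholded, `threshold_applied = 0`).
#' @export
generate_ground_truth_sc <- function(atlas, density_intra = 0.3,
                                     density_inter = 0.05,
                                     homotopic_weight = 0.5,
                                     weight_log_sd = 1, weight_scale = 0.01,
                                     seed = 1) {
  validate_atlas(atlas)
  if (density_intra < 0 || density_intra > 1 || density_inter < 0 ||
      density_inter > 1) {
    stop("densities must be probabilities in [0, 1]", call. = FALSE)
  }
  if (homotopic_weight < 0) stop("homotopic_weight must be >= 0", call. = FALSE)
  if (weight_log_sd <= 0) stop("weight_log_sd must be > 0", call. = FALSE)
  n <- atlas$n_regions
  inter <- interhemispheric_mask(atlas)
  homo <- homotopic_mask(atlas)
  left <- which(atlas$hemisphere == "left")
  right <- which(atlas$hemisphere == "right")
  with_substream(seed, "ground_truth_sc", expr = {
    for (attempt in seq_len(100)) {
      w <- matrix(0, n, n)
      up <- upper.tri(w)
      dens <- ifelse(inter[up], density_inter, density_intra)
      edge <- runif(sum(up)) < dens
      wts <- exp(log(weight_scale) + rnorm(sum(up), 0, weight_log_sd))
      w[up] <- ifelse(edge, wts, 0)
      w <- w + t(w)
      w[homo] <- homotopic_weight
      if (is_connected(w, left) && is_connected(w, right)) {
        return(sc_matrix(w, atlas))
      }
    }
    stop("could not draw connected intra-hemispheric subgraphs; ",
         "increase density_intra", call. = FALSE)
  })
}

#' Generate one subject's measured SC
#'
#' Subject SC = (lognormal global gain) x ground truth + symmetric Gaussian
#' entry noise, clipped at zero, then thresholded at `threshold` (entries
#' below it set to zero, supra-threshold values kept as such). The gain and
#' noise are drawn reproducibly from `(spec$seed, subject_index)`.
#'
#' @param gt Ground-truth `sc_matrix`.
#' @param spec A [cohort_spec()].
#' @param subject_index Subject counter (1-based).
#' @param threshold Detection threshold (default 0.001).
#' @return A thresholded `sc_matrix`. The drawn gain is attached as attribute
#'   `"gain"`.
#' @export
generate_subject_sc <- function(gt, spec, subject_index, threshold = 0.001) {
  n <- gt$atlas$n_regions
  with_substream(spec$seed, "subject_sc", subject_index, expr = {
    g <- exp(rnorm(1, 0, spec$gain_sd))
    noise <- matrix(0, n, n)
    up <- upper.tri(noise)
    noise[up] <- rnorm(sum(up), 0, spec$noise_sd)
    noise <- noise + t(noise)
    w <- pmax(g * gt$weights + noise, 0)
    w[w < threshold] <- 0
    out <- sc_matrix(w, gt$atlas, threshold_applied = threshold)
    attr(out, "gain") <- g
    out
  })
}

#' Suppress interhemispheric connections
#'
#' Emulates diffusion-tractography false negatives: each nonzero
#' interhemispheric (including homotopic) unordered pair is independently set
#' to zero with probability `interhemispheric_miss_rate`; intrahemispheric
#' entries are untouched and symmetry is preserved.
#'
#' @param sc An `sc_matrix`.
#' @param interhemispheric_miss_rate Probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A degraded `sc_matrix`.
#' @export
degrade_sc <- function(sc, interhemispheric_miss_rate, seed = 1) {
  if (interhemispheric_miss_rate < 0 || interhemispheric_miss_rate > 1) {
    stop("interhemispheric_miss_rate must be in [0, 1]", call. = FALSE)
  }
  w <- sc$weights
  inter <- interhemispheric_mask(sc$atlas)
  up <- upper.tri(w) & inter & w > 0
  idx <- which(up)
  with_substream(seed, "degrade_sc", expr = {
    drop <- runif(length(idx)) < interhemispheric_miss_rate
  })
  w[idx[drop]] <- 0
  w <- pmin(w, t(w))  # re-symmetrize: a dropped (i, j) drops (j, i) too
  sc_matrix(w, sc$atlas, threshold_applied = sc$threshold_applied)
}

#' Average SC across a cohort
#'
#' @param cohort List of `sc_matrix` objects on a common atlas.
#' @return The entrywise mean as an `sc_matrix` (threshold 0).
#' @export
average_sc <- function(cohort) {
  w <- Reduce(`+`, lapply(cohort, function(s) s$weights)) / length(cohort)
  sc_matrix(w, cohort[[1]]$atlas)
}

#' Set homotopic connections to a fixed value
#'
#' Used for the manipulation experiment in which all homotopic entries of an
#' (average) SC are artificially set to a common value such as 0.5.
#'
#' @param sc An `sc_matrix`.
#' @param value Nonnegative weight assigned to every homotopic pair.
#' @return An `sc_matrix` with manipulated homotopic entries.
#' @export
set_homotopic_weight <- function(sc, value = 0.5) {
  w <- sc$weights
  w[homotopic_mask(sc$atlas)] <- value
  sc_matrix(w, sc$atlas)
}
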