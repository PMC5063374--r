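#' Log-transform an SC pattern for the SC-FC map
#'
#' Keeps entries at or above `floor` (default `1e-6`) and maps them to
#' `SC' = ln(SC / ref)` with `ref = 1e-4`; sub-floor entries are masked out
#' of the fit. Note that the forward reference constant (1e-4) and the
#' inversion output constant (1e-3, see [invert_fc()]) are kept independently
#' configurable and are not assumed equal.
#'
#' @param sc_pattern Numeric vector of SC values (e.g. the first-dimension
#'   average projection of an SC cohort).
#' @param floor Detection floor; entries below it are masked (default 1e-6).
#' @param ref Reference constant inside the log (default 1e-4).
#' @return A list with `sc_prime` (transformed retained values) and `mask`
#'   (logical vector over the input: `TRUE` = retained).
#' @export
transform_sc <- function(sc_pattern, floor = 1e-6, ref = 1e-4) {
  if (floor <= 0) stop("floor must be > 0", call. = FALSE)
  if (ref <= 0) stop("ref must be > 0", call. = FALSE)
  mask <- is.finite(sc_pattern) & sc_pattern >= floor
  list(sc_prime = log(sc_pattern[mask] / ref), mask = mask)
}

#' Fit the polynomial SC-to-FC map
#'
#' Least-squares polynomial regression `FC ~ P(SC')` of the given order
#' (default 4). "Interpolation" through thousands of scattered points is
#' ill-posed, so the map is fitted, not interpolated.
#'
#' @param sc_prime Transformed SC values (from [transform_sc()]).
#' @param fc_proj Matched FC values (same length).
#' @param order Polynomial order (default 4).
#' @return An object of class `polynomial_map`: coefficients (ascending
#'   powers), `fit_domain`, the central-mass quantiles of `sc_prime` used to
#'   select the inversion branch, and residual summaries.
#' @export
fit_sc_fc_map <- function(sc_prime, fc_proj, order = 4) {
  if (length(sc_prime) != length(fc_proj)) {
    stop("sc_prime and fc_proj must be matched", call. = FALSE)
  }
  if (length(sc_prime) < order + 1) {
    stop("need at least order + 1 points", call. = FALSE)
  }
  if (diff(range(sc_prime)) == 0) stop("degenerate fit domain", call. = FALSE)
  V <- outer(sc_prime, 0:order, `^`)
  beta <- qr.solve(V, fc_proj)
  res <- fc_proj - V %*% beta
  structure(list(
    coefficients = as.numeric(beta),
    order = order,
    fit_domain = range(sc_prime),
    mass_quantiles = unname(quantile(sc_prime, c(0.05, 0.95))),
    residual_sd = sd(res),
    n_points = length(sc_prime)
  ), class = "polynomial_map")
}

#' Evaluate a fitted polynomial map
#' @param map A `polynomial_map`.
#' @param x Points to evaluate at.
#' @return `P(x)`.
#' @export
predict_map <- function(map, x) {
  drop(outer(x, 0:map$order, `^`) %*% map$coefficients)
}

# largest monotone interval of P over the fit domain that covers the central
# 90% of the fitted SC' mass; errors if no single branch covers it
monotone_branch <- function(map) {
  co <- map$coefficients
  dcoef <- co[-1] * seq_len(map$order)
  while (length(dcoef) > 1 && dcoef[length(dcoef)] == 0) {
    dcoef <- dcoef[-length(dcoef)]
  }
  tp <- numeric(0)
  if (length(dcoef) > 1) {
    r <- polyroot(dcoef)
    r <- Re(r[abs(Im(r)) < 1e-8])
    tp <- sort(r[r > map$fit_domain[1] & r < map$fit_domain[2]])
  }
  edges <- c(map$fit_domain[1], tp, map$fit_domain[2])
  lo <- map$mass_quantiles[1]; hi <- map$mass_quantiles[2]
  for (b in seq_len(length(edges) - 1)) {
    if (edges[b] <= lo + 1e-12 && edges[b + 1] >= hi - 1e-12) {
      return(c(edges[b], edges[b + 1]))
    }
  }
  stop("no single monotone branch of the fitted polynomial covers the ",
       "central 90% of the SC' mass; turning points at ",
       paste(signif(tp, 4), collapse = ", "), call. = FALSE)
}

#' Invert the SC-to-FC map
#'
#' Estimates SC from FC values by numerically inverting the fitted polynomial
#' on its monotone branch (dense-grid bracketing plus bisection) and mapping
#' back through the exponential: `SC_hat = ref_out * exp(P^{-1}(FC))`. FC
#' values outside the polynomial's range over the branch are clamped to the
#' boundary and flagged. The output reference constant defaults to `1e-3`,
#' kept independent from the forward `ref` of [transform_sc()].
#'
#' @param fc_pattern Numeric vector of FC values to invert.
#' @param map A fitted `polynomial_map`.
#' @param ref_out Output scale constant (default 0.001).
#' @param tol Bisection tolerance on SC' (default 1e-10).
#' @return Numeric vector of estimated SC values, with attributes `"clamped"`
#'   (logical) and `"sc_prime"` (the inverted SC' values).
#' @export
invert_fc <- function(fc_pattern, map, ref_out = 1e-3, tol = 1e-10) {
  stopifnot(inherits(map, "polynomial_map"))
  br <- monotone_branch(map)
  f <- function(x) predict_map(map, x)
  flo <- f(br[1]); fhi <- f(br[2])
  increasing <- fhi >= flo
  rng <- sort(c(flo, fhi))
  clamped <- fc_pattern < rng[1] | fc_pattern > rng[2]
  target <- pmin(pmax(fc_pattern, rng[1]), rng[2])
  scp <- vapply(target, function(y) {
    if (abs(y - flo) < tol) return(br[1])
    if (abs(y - fhi) < tol) return(br[2])
    a <- br[1]; b <- br[2]
    for (it in 1:200) {
      mid <- (a + b) / 2
      fm <- f(mid)
      if (abs(b - a) < tol) break
      if ((fm < y) == increasing) a <- mid else b <- mid
    }
    (a + b) / 2
  }, numeric(1))
  out <- ref_out * exp(scp)
  attr(out, "clamped") <- clamped
  attr(out, "sc_prime") <- scp
  out
}

#' Estimate structural connectivity from functional connectivity
#'
#' Proof-of-concept inversion of the SC-FC relationship on first-dimension
#' patterns: (1) bootstrap SVD of the (vectorized) SC cohort gives the
#' first-dimension SC pattern; (2) bootstrap SVD of the pooled
#' empirical-plus-simulated FC gives the first-dimension FC pattern; (3) the
#' SC pattern is log-transformed, the polynomial map `FC ~ P(SC')` is fitted
#' on the entries surviving the mask, and (4) the map is inverted on the
#' first-dimension pattern of the empirical FC (the empirical columns'
#' average projection onto the pooled first singular vector). Entries masked
#' out of the fit still receive estimates on inversion -- recovering
#' connections the SC measurement missed is the point -- and are flagged.
#'
#' @param empirical_fc Features x subjects matrix of empirical FC vectors
#'   (column names = subject ids).
#' @param simulated_fc Named list of features x subjects matrices, one per
#'   model (may be empty to fit on empirical FC alone).
#' @param sc_cohort List of per-subject `sc_matrix` objects.
#' @param config List of tuning knobs: `floor` (1e-6), `ref` (1e-4),
#'   `ref_out` (1e-3), `order` (4), `B` (200), `alpha` (0.05), `seed` (1).
#' @return A list of class `sc_estimate`: `weights` (estimated symmetric SC
#'   matrix), `sc_pattern`, `fc_pattern`, `map`, `fit_mask`, `clamped`,
#'   plus the two bootstrap SVD fits.
#' @export
estimate_sc_pipeline <- function(empirical_fc, simulated_fc = list(),
                                 sc_cohort, config = list()) {
  if (is.null(empirical_fc) || ncol(empirical_fc) == 0) {
    stop("empty empirical FC set", call. = FALSE)
  }
  cfg <- list(floor = 1e-6, ref = 1e-4, ref_out = 1e-3, order = 4, B = 200,
              alpha = 0.05, seed = 1)
  cfg[names(config)] <- config
  atlas <- sc_cohort[[1]]$atlas
  subj <- colnames(empirical_fc)
  if (is.null(subj)) subj <- paste0("S", seq_len(ncol(empirical_fc)))

  sc_vecs <- vapply(sc_cohort, function(s) {
    as.numeric(vectorize_upper(s$weights, atlas))
  }, numeric(atlas$n_regions * (atlas$n_regions - 1) / 2))
  colnames(sc_vecs) <- subj[seq_len(ncol(sc_vecs))]
  sc_dm <- data_matrix(sc_vecs, subject = colnames(sc_vecs), source = "sc")
  sc_svd <- bootstrap_svd(sc_dm, B = cfg$B, alpha = cfg$alpha,
                          seed = substream_seed(cfg$seed, "sc_svd"))
  sc_pattern <- average_projection(sc_dm, sc_svd$left_vectors[, 1])

  sources <- c(list(empirical = empirical_fc), simulated_fc)
  pooled <- pool_datasets(sources)
  fc_svd <- bootstrap_svd(pooled, B = cfg$B, alpha = cfg$alpha,
                          seed = substream_seed(cfg$seed, "fc_svd"))
  u1 <- fc_svd$left_vectors[, 1]
  fc_pattern <- average_projection(pooled, u1)
  emp_pattern <- average_projection(pooled, u1, source_filter = "empirical")

  tr <- transform_sc(sc_pattern, floor = cfg$floor, ref = cfg$ref)
  map <- fit_sc_fc_map(tr$sc_prime, fc_pattern[tr$mask], order = cfg$order)
  est <- invert_fc(emp_pattern, map, ref_out = cfg$ref_out)

  cv <- connectivity_vector(as.numeric(est), pair_index(atlas$n_regions),
                            measure = "cFC", n_regions = atlas$n_regions)
  structure(list(
    weights = unvectorize(cv, diag_value = 0),
    estimate = as.numeric(est),
    sc_pattern = sc_pattern,
    fc_pattern = fc_pattern,
    empirical_pattern = emp_pattern,
    map = map,
    fit_mask = tr$mask,
    clamped = attr(est, "clamped"),
    sc_svd = sc_svd,
    fc_svd = fc_svd,
    config = cfg
  ), class = "sc_estimate")
}

#' @export
print.sc_estimate <- function(x, ...) {
  cat(sprintf("sc_estimate: %d entries (%d in fit, %d clamped on inversion)\n",
              length(x$estimate), sum(x$fit_mask), sum(x$clamped)))
  invisible(x)
}
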