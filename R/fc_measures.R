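#' Construct a BOLD run
#'
#' @param values Regions x timepoints numeric matrix, finite, at least 2
#'   timepoints.
#' @param tr Sampling interval in seconds (default 3.29).
#' @param gsr_applied Has the global signal been regressed out already?
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(values, tr = 3.29, gsr_applied = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 timepoints", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  structure(list(values = values, tr = tr, gsr_applied = gsr_applied),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("bold_run: %d regions x %d samples, tr = %g s, GSR %s\n",
              nrow(x$values), ncol(x$values), x$tr,
              if (x$gsr_applied) "applied" else "not applied"))
  invisible(x)
}

#' Global signal regression
#'
#' Regresses the across-region mean time course (plus an intercept) out of
#' each region's series by least squares and returns the residuals. If the
#' global signal is constant, only the intercept is removed (with a warning).
#'
#' @param bold A `bold_run`.
#' @return A `bold_run` with `gsr_applied = TRUE`.
#' @export
global_signal_regression <- function(bold) {
  stopifnot(inherits(bold, "bold_run"))
  Y <- t(bold$values)                    # timepoints x regions
  g <- rowMeans(Y)
  if (sd(g) < .Machine$double.eps^0.5) {
    warning("global signal is constant; regressing on intercept only")
    D <- matrix(1, nrow(Y), 1)
  } else {
    D <- cbind(1, g)
  }
  beta <- solve(crossprod(D), crossprod(D, Y))
  res <- Y - D %*% beta
  bold_run(t(res), tr = bold$tr, gsr_applied = TRUE)
}

#' Pearson functional connectivity
#'
#' Pairwise Pearson correlation between regional time courses.
#'
#' @param bold A `bold_run`.
#' @param drop_zero_variance Zero-variance regions make correlations
#'   undefined; by default that is an error. With `TRUE`, such regions are
#'   dropped and the indices of the dropped regions are attached as attribute
#'   `"dropped"`.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pearson_fc <- function(bold, drop_zero_variance = FALSE) {
  stopifnot(inherits(bold, "bold_run"))
  v <- apply(bold$values, 1, sd)
  bad <- which(v < .Machine$double.eps)
  vals <- bold$values
  if (length(bad)) {
    if (!drop_zero_variance) {
      stop("zero-variance region(s): ", paste(bad, collapse = ", "),
           " (set drop_zero_variance = TRUE to drop them)", call. = FALSE)
    }
    vals <- vals[-bad, , drop = FALSE]
  }
  fc <- cor(t(vals))
  diag(fc) <- 1
  if (length(bad)) attr(fc, "dropped") <- bad
  fc
}

# lexicographic (i < j) pair index for n regions
pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

# lexicographic (i < j < k) triplet index
triplet_index <- function(n) {
  out <- matrix(0L, n * (n - 1L) * (n - 2L) / 6L, 3L)
  colnames(out) <- c("i", "j", "k")
  r <- 1L
  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):(n - 1L)) {
      ks <- (j + 1L):n
      out[r:(r + length(ks) - 1L), ] <- cbind(i, j, ks)
      r <- r + length(ks)
    }
  }
  out
}

#' Construct a connectivity vector
#'
#' A flattened connectivity pattern in the package's canonical order:
#' lexicographic region pairs `(i, j)`, `i < j`, for pairwise measures and
#' lexicographic triplets for 3-way measures; window-concatenated pairs for
#' dynamic FC.
#'
#' @param values Numeric vector.
#' @param index Integer matrix of region pairs/triplets (recycled over
#'   windows for dynamic FC).
#' @param measure One of `"cFC"`, `"mFC"`, `"CT3"`, `"dynFC"`.
#' @param n_regions Number of regions the pattern refers to.
#' @param window_size Window length in samples (dynamic FC only).
#' @return An object of class `connectivity_vector` (a numeric vector with
#'   attributes `index`, `measure`, `n_regions`, `window_size`).
#' @export
connectivity_vector <- function(values, index, measure, n_regions,
                                window_size = NULL) {
  measure <- match.arg(measure, c("cFC", "mFC", "CT3", "dynFC"))
  n_win <- if (measure == "dynFC") length(values) / nrow(index) else 1
  if (length(values) != nrow(index) * n_win) {
    stop("values length does not match index", call. = FALSE)
  }
  structure(as.numeric(values), index = index, measure = measure,
            n_regions = as.integer(n_regions), window_size = window_size,
            class = "connectivity_vector")
}

#' @export
print.connectivity_vector <- function(x, ...) {
  cat(sprintf("connectivity_vector (%s): %d coefficients, %d regions\n",
              attr(x, "measure"), length(x), attr(x, "n_regions")))
  invisible(x)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Flattens a square symmetric matrix into the canonical lexicographic
#' `(i, j)`, `i < j` order. With `subset = "intrahemispheric"` only pairs
#' lying within one hemisphere are kept (an atlas is then required).
#'
#' @param m Square numeric matrix.
#' @param atlas Optional `region_atlas` (required for the intrahemispheric
#'   subset).
#' @param subset `"all"` or `"intrahemispheric"`.
#' @param measure Measure tag for the result (default `"cFC"`).
#' @return A `connectivity_vector`.
#' @export
vectorize_upper <- function(m, atlas = NULL, subset = c("all", "intrahemispheric"),
                            measure = "cFC") {
  subset <- match.arg(subset)
  n <- nrow(m)
  idx <- pair_index(n)
  if (subset == "intrahemispheric") {
    if (is.null(atlas)) stop("intrahemispheric subset needs an atlas", call. = FALSE)
    keep <- atlas$hemisphere[idx[, 1]] == atlas$hemisphere[idx[, 2]]
    idx <- idx[keep, , drop = FALSE]
  }
  connectivity_vector(m[idx], idx, measure = measure, n_regions = n)
}

#' Rebuild a symmetric matrix from a vectorized pattern
#'
#' Inverse of [vectorize_upper()] for the `"all"` subset; for subset patterns
#' the missing entries are filled with `fill`.
#'
#' @param v A `connectivity_vector` (pairwise) or plain vector with `index`.
#' @param n_regions Number of regions (taken from the vector's attribute if
#'   absent).
#' @param diag_value Value placed on the diagonal (default 0).
#' @param fill Value for entries not covered by the index (default `NA`).
#' @return A symmetric `n x n` matrix.
#' @export
unvectorize <- function(v, n_regions = attr(v, "n_regions"), diag_value = 0,
                        fill = NA_real_) {
  idx <- attr(v, "index")
  if (is.null(idx)) stop("v carries no pair index", call. = FALSE)
  m <- matrix(fill, n_regions, n_regions)
  m[idx] <- as.numeric(v)
  m[idx[, c(2, 1)]] <- as.numeric(v)
  diag(m) <- diag_value
  m
}

#' Mutual information of a bivariate Gaussian
#'
#' Closed form `-1/2 * log(1 - rho^2)` (in nats) for the mutual information
#' of two jointly Gaussian variables with correlation `rho`. Symmetric in
#' `+/- rho` and increasing in `|rho|`.
#'
#' @param rho Correlation(s) in `(-1, 1)`.
#' @return Mutual information in nats.
#' @export
gaussian_mi <- function(rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  -0.5 * log(1 - rho^2)
}

#' Total correlation of a trivariate Gaussian
#'
#' Closed form `-1/2 * log det(R)` for the 3-way total correlation of jointly
#' Gaussian variables with correlation matrix `R`, computed via the expanded
#' determinant `1 + 2*rij*rjk*rik - (rij^2 + rjk^2 + rik^2)`. The triple must
#' form a positive-definite correlation matrix.
#'
#' @param rho_ij,rho_jk,rho_ik Pairwise correlations (vectorized).
#' @return Total correlation in nats.
#' @export
gaussian_ct3 <- function(rho_ij, rho_jk, rho_ik) {
  if (any(abs(c(rho_ij, rho_jk, rho_ik)) >= 1)) {
    stop("|rho| must be < 1", call. = FALSE)
  }
  det3 <- 1 + 2 * rho_ij * rho_jk * rho_ik - (rho_ij^2 + rho_jk^2 + rho_ik^2)
  if (any(det3 <= 0)) {
    stop("correlation triple is not positive definite", call. = FALSE)
  }
  -0.5 * log(det3)
}

#' k-nearest-neighbour mutual information
#'
#' Kraskov-type (algorithm 1) kNN estimate of the mutual information between
#' two continuous samples, in nats. The estimator is deterministic in its
#' inputs (strict-inequality neighbour counts, no jitter); small negative
#' values are a known finite-sample artifact and are retained, not clipped.
#'
#' @param x,y Numeric sample vectors of equal length.
#' @param k Neighbour count (default 4), must be below the sample size.
#' @return Estimated mutual information in nats.
#' @export
knn_mutual_information <- function(x, y, k = 4) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (k >= length(x) || k < 1) stop("need 1 <= k < sample size", call. = FALSE)
  .ksg_multiinfo_cpp(cbind(x, y), as.integer(k))
}

#' k-nearest-neighbour total correlation
#'
#' Kraskov-type kNN estimate of the multiinformation (total correlation) of
#' the columns of `x`, in nats; with two columns this is the mutual
#' information, with three the 3-way total correlation.
#'
#' @param x Numeric matrix, samples x variables.
#' @param k Neighbour count (default 4).
#' @return Estimated total correlation in nats.
#' @export
knn_total_correlation <- function(x, k = 4) {
  x <- as.matrix(x)
  if (k >= nrow(x) || k < 1) stop("need 1 <= k < sample size", call. = FALSE)
  .ksg_multiinfo_cpp(x, as.integer(k))
}

#' Mutual-information functional connectivity
#'
#' kNN mutual information for every region pair, in canonical order.
#'
#' @param bold A `bold_run`.
#' @param k Neighbour count (default 4).
#' @return A `connectivity_vector` (measure `"mFC"`).
#' @export
mi_fc <- function(bold, k = 4) {
  stopifnot(inherits(bold, "bold_run"))
  n <- nrow(bold$values)
  vals <- .ksg_all_pairs_cpp(t(bold$values), as.integer(k))
  connectivity_vector(vals, pair_index(n), measure = "mFC", n_regions = n)
}

#' Three-way total-correlation connectivity
#'
#' kNN total correlation for every region triplet `(i < j < k)`, in
#' lexicographic order. The triplet count grows as `C(n, 3)` (669 920 already
#' at 160 regions), which makes this the costliest measure by far; above
#' `max_triplets` the call errors unless `allow_large = TRUE`.
#'
#' @param bold A `bold_run`.
#' @param k Neighbour count (default 4).
#' @param allow_large Allow more than `max_triplets` triplets.
#' @param max_triplets Guard threshold (default 20000).
#' @return A `connectivity_vector` (measure `"CT3"`).
#' @export
ct3 <- function(bold, k = 4, allow_large = FALSE, max_triplets = 20000) {
  stopifnot(inherits(bold, "bold_run"))
  n <- nrow(bold$values)
  n_tri <- choose(n, 3)
  if (n_tri > max_triplets && !allow_large) {
    stop(sprintf("%d triplets requested; set allow_large = TRUE to proceed",
                 n_tri), call. = FALSE)
  }
  vals <- .ksg_all_triplets_cpp(t(bold$values), as.integer(k))
  connectivity_vector(vals, triplet_index(n), measure = "CT3", n_regions = n)
}

#' Windowed (dynamic) functional connectivity
#'
#' Splits the run into non-overlapping windows of `window_size` samples,
#' computes Pearson FC on each window, vectorizes canonically and
#' concatenates in temporal order.
#'
#' @param bold A `bold_run`.
#' @param window_size Samples per window; must divide the run length unless
#'   `truncate = TRUE`, in which case the remainder at the end is dropped.
#' @param truncate Allow a trailing partial window to be discarded.
#' @return A `connectivity_vector` (measure `"dynFC"`) with attribute
#'   `n_windows`; its length is `n_windows * choose(n, 2)`.
#' @export
dynamic_fc <- function(bold, window_size, truncate = FALSE) {
  stopifnot(inherits(bold, "bold_run"))
  Tn <- ncol(bold$values)
  if (window_size < 2 || window_size > Tn) {
    stop("window_size must be in [2, run length]", call. = FALSE)
  }
  if (Tn %% window_size != 0 && !truncate) {
    stop("window_size does not divide the run length ",
         "(set truncate = TRUE to drop the tail)", call. = FALSE)
  }
  n_win <- Tn %/% window_size
  n <- nrow(bold$values)
  idx <- pair_index(n)
  vals <- unlist(lapply(seq_len(n_win), function(w) {
    cols <- ((w - 1) * window_size + 1):(w * window_size)
    fc <- pearson_fc(bold_run(bold$values[, cols, drop = FALSE], tr = bold$tr,
                              gsr_applied = bold$gsr_applied))
    fc[idx]
  }), use.names = FALSE)
  out <- connectivity_vector(vals, idx, measure = "dynFC", n_regions = n,
                             window_size = as.integer(window_size))
  attr(out, "n_windows") <- n_win
  out
}
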