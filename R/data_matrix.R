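#' Assemble a features-by-observations data matrix
#'
#' The common container for every SVD analysis: columns are observations
#' (subject, or subject-by-source when empirical and simulated patterns are
#' pooled), rows are features (connectivity coefficients or flattened BOLD
#' samples). Bootstrap resampling operates on the subject labels, so all
#' columns of one subject always move together.
#'
#' @param X Numeric matrix (features x observations), finite entries.
#' @param subject Character/integer vector of per-column subject ids.
#' @param source Per-column source tag (e.g. `"empirical"` or a model name);
#'   recycled if scalar.
#' @param feature_meta Optional description of the row space (e.g. the pair
#'   index of a connectivity vector), carried along for reshaping patterns.
#' @return An object of class `scfc_data_matrix`.
#' @export
data_matrix <- function(X, subject, source = "empirical", feature_meta = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must have finite entries", call. = FALSE)
  subject <- as.character(subject)
  if (length(subject) != ncol(X) || any(!nzchar(subject))) {
    stop("subject must give one non-empty id per column", call. = FALSE)
  }
  source <- rep_len(as.character(source), ncol(X))
  structure(list(X = X, subject = subject, source = source,
                 feature_meta = feature_meta),
            class = "scfc_data_matrix")
}

#' @export
print.scfc_data_matrix <- function(x, ...) {
  cat(sprintf("scfc_data_matrix: %d features x %d observations (%d subjects, sources: %s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$subject)),
              paste(unique(x$source), collapse = ", ")))
  invisible(x)
}

#' Plant a low-rank dataset with prescribed variance fractions
#'
#' Builds `X = sum_{i<=rank} s_i u_i v_i' + noise` with orthonormal `u_i`,
#' `v_i`. The singular values are set so that each signal dimension accounts
#' for the requested fraction of the total (signal + expected noise) sum of
#' squares: with `sum(fractions) < 1` the i.i.d. noise supplies the remaining
#' share. With `noise_sd = 0` the fractions must sum to 1 and the matrix is
#' exactly rank `rank`.
#'
#' The feature-space directions `u_i` are random orthonormal vectors, but the
#' observation loadings `v_i` are jittered sign patterns of near-constant
#' magnitude (`~ 1/sqrt(m)` per subject): dimension 1 is a common core shared
#' by every subject and further dimensions are balanced contrasts. This is
#' the structure the subject-bootstrap analyses assume; with loadings
#' concentrated on a few subjects, resampling subjects would make singular
#' values arbitrarily unstable regardless of the planted rank.
#'
#' @param n_features,n_observations Matrix dimensions.
#' @param rank Number of planted dimensions.
#' @param variance_fractions Positive fractions, one per planted dimension,
#'   summing to at most 1.
#' @param noise_sd SD of the i.i.d. Gaussian noise.
#' @param seed Integer seed.
#' @return An `scfc_data_matrix` (source `"planted"`, subjects `S1..Sm`) with
#'   attribute `"ground_truth"` recording rank, fractions, singular values and
#'   the planted `u_i`.
#' @export
planted_lowrank_dataset <- function(n_features, n_observations, rank,
                                    variance_fractions, noise_sd, seed = 1) {
  if (length(variance_fractions) != rank || any(variance_fractions <= 0)) {
    stop("need one positive variance fraction per planted dimension",
         call. = FALSE)
  }
  fsum <- sum(variance_fractions)
  if (fsum > 1 + 1e-12) stop("variance fractions must sum to <= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd == 0 && abs(fsum - 1) > 1e-12) {
    stop("with noise_sd = 0 the fractions must sum to 1", call. = FALSE)
  }
  n <- n_features; m <- n_observations
  if (rank > min(n, m)) stop("rank exceeds matrix dimensions", call. = FALSE)
  with_substream(seed, "planted_lowrank", expr = {
    u <- qr.Q(qr(matrix(rnorm(n * rank), n, rank)))
    # near-constant-magnitude loadings: common core + balanced sign contrasts
    V0 <- matrix(1, m, rank)
    for (i in seq_len(rank)[-1]) {
      V0[, i] <- ifelse(((seq_len(m) - 1) %/% 2^(i - 2)) %% 2 == 0, 1, -1)
    }
    V0 <- V0 + matrix(rnorm(m * rank, 0, 0.1), m, rank)
    v <- qr.Q(qr(V0))
    # orient each planted u_i to have positive mean entry
    for (i in seq_len(rank)) {
      if (mean(u[, i]) < 0) { u[, i] <- -u[, i]; v[, i] <- -v[, i] }
    }
    noise_ss <- n * m * noise_sd^2
    total_ss <- if (noise_sd > 0) noise_ss / (1 - fsum) else n  # scale is arbitrary
    s <- sqrt(variance_fractions * total_ss)
    X <- u %*% (s * t(v))
    if (noise_sd > 0) X <- X + matrix(rnorm(n * m, 0, noise_sd), n, m)
    out <- data_matrix(X, subject = paste0("S", seq_len(m)), source = "planted")
    attr(out, "ground_truth") <- list(rank = rank,
                                      variance_fractions = variance_fractions,
                                      singular_values = s, u = u)
    out
  })
}

#' Flatten per-subject BOLD runs into a data matrix
#'
#' Each subject's regions-by-timepoints matrix becomes one column, flattened
#' region-fastest (column `j` holds `c(values[, 1], values[, 2], ...)`, i.e.
#' all regions at timepoint 1, then all regions at timepoint 2, ...).
#'
#' @param runs Named list of `bold_run` objects, one per subject, with equal
#'   dimensions; names are the subject ids.
#' @return An `scfc_data_matrix` with `feature_meta` recording the (region,
#'   timepoint) grid so columns can be unflattened.
#' @export
bold_to_datamatrix <- function(runs) {
  dims <- vapply(runs, function(r) dim(r$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all runs must share the same dimensions", call. = FALSE)
  }
  ids <- names(runs)
  if (is.null(ids)) ids <- paste0("S", seq_along(runs))
  X <- vapply(runs, function(r) as.vector(r$values),
              numeric(dims[1, 1] * dims[2, 1]))
  data_matrix(X, subject = ids, source = "bold",
              feature_meta = list(type = "bold", n_regions = dims[1, 1],
                                  n_timepoints = dims[2, 1]))
}

#' Reshape a flattened BOLD feature vector back to regions x timepoints
#'
#' @param x Feature vector produced by [bold_to_datamatrix()] flattening.
#' @param feature_meta The `feature_meta` of the data matrix.
#' @return A regions x timepoints matrix.
#' @export
unflatten_bold <- function(x, feature_meta) {
  matrix(x, feature_meta$n_regions, feature_meta$n_timepoints)
}
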