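#' Uncentered SVD variance decomposition
#'
#' Decomposes `X = U S V'` without removing any mean: the first dimension of
#' connectivity cohorts is a common positive core whose subjects differ by a
#' global multiplicative constant, and centering would subtract exactly that
#' structure. The variance fraction of dimension `i` is `s_i^2 / sum_j s_j^2`,
#' so fractions always sum to 1. Each left-singular vector is oriented so that
#' its mean entry is positive (the SVD sign ambiguity), with the corresponding
#' right-singular vector flipped to match.
#'
#' @param X An `scfc_data_matrix` or a plain numeric matrix.
#' @return A list with `singular_values` (nonincreasing), `variance_fractions`,
#'   `left_vectors` (n x m), `right_vectors` (m x m).
#' @export
svd_variance <- function(X) {
  M <- if (inherits(X, "scfc_data_matrix")) X$X else as.matrix(X)
  if (any(!is.finite(M))) stop("X must have finite entries", call. = FALSE)
  sv <- svd(M, nu = min(dim(M)), nv = ncol(M))
  flip <- vapply(seq_len(ncol(sv$u)), function(i) mean(sv$u[, i]) < 0, logical(1))
  sv$u[, flip] <- -sv$u[, flip, drop = FALSE]
  sv$v[, flip] <- -sv$v[, flip, drop = FALSE]
  list(singular_values = sv$d,
       variance_fractions = sv$d^2 / sum(sv$d^2),
       left_vectors = sv$u,
       right_vectors = sv$v)
}

#' Number of reproducible dimensions from singular-value confidence intervals
#'
#' A dimension is declared reproducible when the bootstrap confidence interval
#' of its singular value does not overlap with that of the next one. Under the
#' default `"contiguous"` rule, `d` is the largest index such that the
#' separation holds for every `i <= d` (so `d = 0` as soon as the first pair
#' overlaps). The `"last"` rule instead returns the last separated pair
#' regardless of earlier overlaps.
#'
#' @param ci_low,ci_high Per-singular-value interval bounds (ordered by
#'   decreasing singular value).
#' @param rule `"contiguous"` (default) or `"last"`.
#' @return Integer dimension `d >= 0`.
#' @export
reproducible_dimension <- function(ci_low, ci_high,
                                   rule = c("contiguous", "last")) {
  rule <- match.arg(rule)
  m <- length(ci_low)
  if (m < 2) return(0L)
  sep <- ci_low[-m] > ci_high[-1]  # interval i entirely above interval i+1
  if (!any(sep)) return(0L)
  if (rule == "contiguous") {
    if (!sep[1]) return(0L)
    d <- which(!sep)[1] - 1L
    if (is.na(d)) d <- length(sep)
  } else {
    d <- max(which(sep))
  }
  as.integer(d)
}

#' Bootstrap SVD over subjects
#'
#' Resamples subjects with replacement `B` times; each replicate keeps all
#' columns of every drawn subject (a subject drawn twice contributes its
#' columns twice) and is decomposed by uncentered SVD. Percentile confidence
#' intervals on the singular values determine the reproducible dimension; the
#' same intervals are also reported for the variance fractions, since summary
#' statistics are conventionally quoted on that scale. Replicates that draw a
#' single distinct subject are redrawn (and counted). The result is fully
#' determined by `seed`.
#'
#' @param X An `scfc_data_matrix` with at least 3 distinct subjects.
#' @param B Number of bootstrap replicates (default 1000; below 100 a warning
#'   is issued).
#' @param alpha Two-sided percentile CI level (default 0.05, i.e. 95% CIs).
#' @param seed Integer seed.
#' @param rule Dimension rule, see [reproducible_dimension()].
#' @return An object of class `bootstrap_svd` with the full-data decomposition
#'   (`singular_values`, `variance_fractions`, `left_vectors`), the bootstrap
#'   summaries (`ci_low`, `ci_high`, `fraction_ci_low`, `fraction_ci_high`,
#'   `bootstrap_fraction_mean`, `bootstrap_fraction_sd`,
#'   `bootstrap_sv_mean`, `bootstrap_sv_sd`), `reproducible_dim`, and the
#'   average projection of the data onto each reproducible dimension
#'   (`avg_projection`, a list of feature-space patterns).
#' @export
bootstrap_svd <- function(X, B = 1000, alpha = 0.05, seed = 1,
                          rule = c("contiguous", "last")) {
  rule <- match.arg(rule)
  stopifnot(inherits(X, "scfc_data_matrix"))
  subjects <- unique(X$subject)
  if (length(subjects) < 3) stop("need at least 3 distinct subjects", call. = FALSE)
  if (B < 100) warning("B < 100 gives unstable confidence intervals")
  M <- X$X
  m <- ncol(M)
  full <- svd_variance(M)
  # Gram matrix once; a replicate's singular values are the root eigenvalues
  # of the corresponding submatrix of G (columns enter by index).
  G <- crossprod(M)
  cols_of <- split(seq_len(m), X$subject)[subjects]
  n_sub <- length(subjects)
  sv_boot <- matrix(NA_real_, B, m)
  redrawn <- 0L
  with_substream(seed, "bootstrap_svd", expr = {
    for (b in seq_len(B)) {
      repeat {
        draw <- sample.int(n_sub, n_sub, replace = TRUE)
        if (length(unique(draw)) > 1) break
        redrawn <- redrawn + 1L
      }
      idx <- unlist(cols_of[draw], use.names = FALSE)
      ev <- eigen(G[idx, idx, drop = FALSE], symmetric = TRUE,
                  only.values = TRUE)$values
      ev <- pmax(ev, 0)
      s <- sqrt(ev)
      sv_boot[b, seq_len(min(m, length(s)))] <- s[seq_len(min(m, length(s)))]
    }
  })
  k <- max(which(colSums(!is.na(sv_boot)) == B))  # dims present in all replicates
  sv_boot <- sv_boot[, seq_len(k), drop = FALSE]
  frac_boot <- sv_boot^2 / rowSums(sv_boot^2)
  probs <- c(alpha / 2, 1 - alpha / 2)
  ci <- apply(sv_boot, 2, quantile, probs = probs, names = FALSE)
  fci <- apply(frac_boot, 2, quantile, probs = probs, names = FALSE)
  d <- reproducible_dimension(ci[1, ], ci[2, ], rule = rule)
  d <- min(d, m - 1L)
  proj <- lapply(seq_len(d), function(i) {
    average_projection(X, full$left_vectors[, i])
  })
  structure(list(
    singular_values = full$singular_values,
    variance_fractions = full$variance_fractions,
    left_vectors = full$left_vectors,
    ci_low = ci[1, ], ci_high = ci[2, ],
    fraction_ci_low = fci[1, ], fraction_ci_high = fci[2, ],
    bootstrap_fraction_mean = colMeans(frac_boot),
    bootstrap_fraction_sd = apply(frac_boot, 2, sd),
    bootstrap_sv_mean = colMeans(sv_boot),
    bootstrap_sv_sd = apply(sv_boot, 2, sd),
    reproducible_dim = d,
    avg_projection = proj,
    B = B, alpha = alpha, rule = rule, redrawn = redrawn,
    feature_meta = X$feature_meta
  ), class = "bootstrap_svd")
}

#' @export
print.bootstrap_svd <- function(x, ...) {
  cat(sprintf("bootstrap_svd: B = %d, reproducible dimension d = %d\n",
              x$B, x$reproducible_dim))
  k <- min(max(x$reproducible_dim, 3), length(x$bootstrap_fraction_mean))
  for (i in seq_len(k)) {
    cat(sprintf("  dim %d: %.1f%% +/- %.1f%% of variance%s\n", i,
                100 * x$bootstrap_fraction_mean[i],
                100 * x$bootstrap_fraction_sd[i],
                if (i <= x$reproducible_dim) " (reproducible)" else ""))
  }
  invisible(x)
}

#' Average projection of the data onto a singular vector
#'
#' The representative pattern along dimension `i`: the left-singular vector
#' `u_i` scaled by the mean projection of the columns onto it,
#' `(1/m) sum_j u_i' x_j * u_i` (averaging and projection commute, so this
#' equals the projection of the average column). When empirical and simulated
#' data are pooled, a `source_filter` restricts the mean to the tagged
#' columns, e.g. to characterize a dimension by the empirical data only.
#'
#' @param X An `scfc_data_matrix`.
#' @param u A unit feature-space vector (e.g. a column of `left_vectors`).
#' @param source_filter Optional source tag; only matching columns enter the
#'   mean.
#' @return A numeric feature-space pattern.
#' @export
average_projection <- function(X, u, source_filter = NULL) {
  stopifnot(inherits(X, "scfc_data_matrix"))
  keep <- if (is.null(source_filter)) rep(TRUE, ncol(X$X)) else X$source == source_filter
  if (!any(keep)) stop("source_filter matches no columns", call. = FALSE)
  drop(mean(crossprod(X$X[, keep, drop = FALSE], u)) * u)
}

#' Permutation controls for connectivity cohorts
#'
#' Destroys, per subject, the anatomical labelling that the low-dimensional
#' structure is suspected to rest on. `mode = "links"` permutes the entries of
#' each subject's vectorized connectivity pattern; `"regions"` permutes the
#' region labels of the square matrix and re-vectorizes; `"within_hemisphere"`
#' draws one permutation of the left-hemisphere labels and applies it to both
#' hemispheres simultaneously, preserving the homotopic pairing. Permutations
#' are independent across subjects.
#'
#' @param matrices Named list of per-subject square connectivity matrices
#'   (names are subject ids).
#' @param atlas The `region_atlas` the matrices live on.
#' @param mode One of `"links"`, `"regions"`, `"within_hemisphere"`.
#' @param seed Integer seed.
#' @param permutations Optional test hook: list (one per subject) of explicit
#'   permutations to use instead of random ones (of the links for `"links"`,
#'   of the regions for `"regions"`, of one hemisphere's labels for
#'   `"within_hemisphere"`).
#' @return An `scfc_data_matrix` of permuted vectorized patterns.
#' @export
permute_dataset <- function(matrices, atlas,
                            mode = c("links", "regions", "within_hemisphere"),
                            seed = 1, permutations = NULL) {
  mode <- match.arg(mode)
  validate_atlas(atlas)
  n <- atlas$n_regions
  h <- n %/% 2L
  ids <- names(matrices)
  if (is.null(ids)) ids <- paste0("S", seq_along(matrices))
  n_links <- n * (n - 1) / 2
  cols <- vector("list", length(matrices))
  with_substream(seed, "permute", mode, expr = {
    for (j in seq_along(matrices)) {
      M <- matrices[[j]]
      if (mode == "links") {
        v <- vectorize_upper(M, atlas)
        p <- if (is.null(permutations)) sample.int(n_links) else permutations[[j]]
        cols[[j]] <- as.numeric(v)[p]
      } else {
        p <- if (mode == "regions") {
          if (is.null(permutations)) sample.int(n) else permutations[[j]]
        } else {
          ph <- if (is.null(permutations)) sample.int(h) else permutations[[j]]
          c(ph, ph + h)  # same relabelling on both sides keeps homotopic pairs
        }
        cols[[j]] <- as.numeric(vectorize_upper(M[p, p, drop = FALSE], atlas))
      }
    }
  })
  data_matrix(do.call(cbind, cols), subject = ids,
              source = paste0("permuted_", mode),
              feature_meta = list(type = "pairs", n_regions = n))
}

#' Pool connectivity patterns from several sources
#'
#' Stacks per-subject pattern matrices from several sources (e.g. empirical
#' plus one per generative model) into one data matrix. Columns are ordered by
#' subject, then source, and keep their subject ids so that bootstrap
#' resampling moves all of a subject's columns together.
#'
#' @param sources Named list; each element is a features x subjects matrix
#'   with subject ids as column names (all sources must agree on features and
#'   subjects).
#' @return An `scfc_data_matrix` whose `source` tags are the list names.
#' @export
pool_datasets <- function(sources) {
  stopifnot(is.list(sources), length(sources) >= 1, !is.null(names(sources)))
  nf <- vapply(sources, nrow, integer(1))
  if (any(nf != nf[1])) stop("sources differ in feature length", call. = FALSE)
  subj <- colnames(sources[[1]])
  if (is.null(subj)) subj <- paste0("S", seq_len(ncol(sources[[1]])))
  for (s in sources) {
    if (ncol(s) != length(subj)) stop("sources differ in subjects", call. = FALSE)
  }
  tags <- names(sources)
  cols <- list(); subject <- character(); source <- character()
  for (s_i in seq_along(subj)) {
    for (t_i in seq_along(tags)) {
      cols[[length(cols) + 1L]] <- sources[[t_i]][, s_i]
      subject <- c(subject, subj[s_i])
      source <- c(source, tags[t_i])
    }
  }
  data_matrix(do.call(cbind, cols), subject = subject, source = source)
}

#' Residual connectivity: empirical minus simulated
#'
#' One column per (subject, model): the difference between the subject's
#' empirical pattern and the pattern simulated for that subject under that
#' model. With 21 subjects and 7 models this yields 147 residual patterns.
#'
#' @param empirical Features x subjects matrix (column names = subject ids).
#' @param simulated Named list of features x subjects matrices, one per model.
#' @return An `scfc_data_matrix` with `source` = model name.
#' @export
residual_fc <- function(empirical, simulated) {
  stopifnot(is.list(simulated), !is.null(names(simulated)))
  subj <- colnames(empirical)
  if (is.null(subj)) subj <- paste0("S", seq_len(ncol(empirical)))
  cols <- list(); subject <- character(); source <- character()
  for (s_i in seq_along(subj)) {
    for (mod in names(simulated)) {
      sim <- simulated[[mod]]
      if (!all(dim(sim) == dim(empirical))) {
        stop("simulated and empirical dimensions differ", call. = FALSE)
      }
      cols[[length(cols) + 1L]] <- empirical[, s_i] - sim[, s_i]
      subject <- c(subject, subj[s_i])
      source <- c(source, mod)
    }
  }
  data_matrix(do.call(cbind, cols), subject = subject, source = source)
}
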