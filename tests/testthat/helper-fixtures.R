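# Small programmatic fixtures shared across the suite.

# a compact connected SC for fast model tests
tiny_sc <- function(n = 6, seed = 2) {
  atlas <- generate_atlas(n)
  generate_ground_truth_sc(atlas, density_intra = 0.8, density_inter = 0.3,
                           homotopic_weight = 0.5, weight_log_sd = 1,
                           seed = seed)
}

# correlated Gaussian pair with exact population correlation rho
gaussian_pair <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y)
}

# cohort of symmetric rank-1 connectivity matrices (subject = global gain).
# Entries are zero-mean, like FC residuals after global signal regression;
# a pattern with a large common mean would survive entry permutation as a
# shared constant component and the destruction tests would be meaningless.
rank1_matrix_cohort <- function(n_regions, n_subjects, gain_sd = 0.2,
                                seed = 1) {
  set.seed(seed)
  base <- matrix(0, n_regions, n_regions)
  up <- upper.tri(base)
  base[up] <- rnorm(sum(up))
  base <- base + t(base)
  gains <- exp(rnorm(n_subjects, 0, gain_sd))
  out <- lapply(gains, function(g) g * base)
  names(out) <- paste0("S", seq_len(n_subjects))
  out
}

# random positive-definite 3x3 correlation matrix with pairwise correlations
# of moderate strength (redrawn until positive definite)
random_moderate_cor3 <- function() {
  repeat {
    r <- runif(3, -0.5, 0.7)
    R <- diag(3)
    R[lower.tri(R)] <- r
    R[upper.tri(R)] <- t(R)[upper.tri(R)]
    if (min(eigen(R, only.values = TRUE)$values) > 0.05) return(R)
  }
}

# reference Euler integration of the hemodynamic system at a finer step;
# independent of the compiled path (plain R, substepped)
reference_bw <- function(neural, dt, par = hemodynamic_params(), substeps = 10) {
  k1 <- 7 * par$E0; k2 <- 2; k3 <- 2 * par$E0 - 0.2
  n <- nrow(neural); T <- ncol(neural)
  out <- matrix(0, n, T)
  h <- dt / substeps
  for (i in seq_len(n)) {
    s <- 0; f <- 1; v <- 1; q <- 1
    for (t in seq_len(T)) {
      z <- neural[i, t]
      for (ss in seq_len(substeps)) {
        Ef <- 1 - (1 - par$E0)^(1 / f)
        fv <- v^(1 / par$alpha)
        ds <- z - par$kappa * s - par$gamma * (f - 1)
        df <- s
        dv <- (f - fv) / par$tau
        dq <- (f * Ef / par$E0 - fv * q / v) / par$tau
        s <- s + ds * h; f <- f + df * h; v <- v + dv * h; q <- q + dq * h
      }
      out[i, t] <- 100 * par$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
    }
  }
  out
}
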