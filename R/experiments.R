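`%||%` <- function(a, b) if (is.null(a)) b else a

#' Names of the bundled experiments
#' @return Character vector of experiment tags.
#' @export
experiment_tags <- function() {
  c("d1_sc", "d1_cfc", "d1_mfc", "d1_ct3", "d1_bold", "d2_nogsr",
    "d5_permutations", "d6_simulated", "d7_pooled", "d8_intrahemispheric",
    "d9_residual", "d10_average_subject", "d11_dynamic")
}

#' Configure a synthetic-cohort experiment suite
#'
#' Desk-scale defaults: a 40-region atlas, 5 subjects, 200 BOLD volumes at
#' 3.29 s, three generative models and 200 bootstrap replicates; the full
#' scale of the scientific setting (160 regions, 21 subjects, B = 1000)
#' is reached by overriding the corresponding fields. The "empirical"
#' surrogate data are BOLD runs simulated from each subject's intact SC under
#' `empirical_model`; the "simulated" patterns are produced by the model list
#' driven by the degraded (diffusion-style, interhemisphere-depleted) SC, so
#' the empirical-minus-simulated contrasts probe exactly the missing
#' interhemispheric structure.
#'
#' @param n_regions,n_subjects,n_samples,tr Cohort and run geometry.
#' @param models Generative models used for simulated FC.
#' @param empirical_model Model generating the empirical surrogate BOLD.
#' @param couplings Optional named couplings per model (model defaults
#'   otherwise).
#' @param B,alpha Bootstrap replicates and CI level.
#' @param k kNN neighbour count for information-based FC.
#' @param windows Dynamic-FC window sizes in samples.
#' @param gain_sd,noise_sd,interhemispheric_miss_rate Cohort spec, see
#'   [cohort_spec()].
#' @param density_intra,density_inter,homotopic_weight,weight_log_sd,weight_scale
#'   Ground-truth SC parameters, see [generate_ground_truth_sc()].
#' @param homotopic_value Value planted on homotopic links in the
#'   manipulation experiment (default 0.5).
#' @param seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_regions = 40, n_subjects = 5, n_samples = 200,
                              tr = 3.29, models = c("sar", "kuramoto", "rate"),
                              empirical_model = "rate", couplings = NULL,
                              B = 200, alpha = 0.05, k = 4,
                              windows = c(8, 10, 20, 25, 40, 50, 100),
                              gain_sd = 0.2, noise_sd = 0.002,
                              interhemispheric_miss_rate = 0.8,
                              density_intra = 0.3, density_inter = 0.05,
                              homotopic_weight = 0.5, weight_log_sd = 1,
                              weight_scale = 0.01, homotopic_value = 0.5,
                              seed = 1) {
  structure(as.list(environment()), class = "experiment_config")
}

make_model_config <- function(config, model, seed_tags) {
  g <- config$couplings[[model]] %||% default_coupling(model)
  model_config(model, global_coupling = g,
               seed = do.call(substream_seed, c(list(config$seed), seed_tags)))
}

#' Build (lazily) the shared data of an experiment suite
#'
#' Returns a memoizing context holding the cohort, the empirical-surrogate
#' BOLD runs and the per-model simulated FC. Pass it to several
#' [run_experiment()] calls to avoid re-simulating between experiments.
#'
#' @param config An [experiment_config()].
#' @return An environment of class `experiment_context`.
#' @export
build_experiment_context <- function(config) {
  ctx <- new.env(parent = emptyenv())
  ctx$config <- config
  class(ctx) <- "experiment_context"
  ctx
}

ctx_get <- function(ctx, key, builder) {
  if (is.null(ctx[[key]])) ctx[[key]] <- builder()
  ctx[[key]]
}

ctx_atlas <- function(ctx) {
  ctx_get(ctx, "atlas", function() generate_atlas(ctx$config$n_regions))
}

ctx_gt <- function(ctx) {
  ctx_get(ctx, "gt", function() {
    cf <- ctx$config
    generate_ground_truth_sc(ctx_atlas(ctx), density_intra = cf$density_intra,
                             density_inter = cf$density_inter,
                             homotopic_weight = cf$homotopic_weight,
                             weight_log_sd = cf$weight_log_sd,
                             weight_scale = cf$weight_scale,
                             seed = substream_seed(cf$seed, "gt"))
  })
}

ctx_subject_sc <- function(ctx) {
  ctx_get(ctx, "subject_sc", function() {
    cf <- ctx$config
    spec <- cohort_spec(cf$n_subjects, gain_sd = cf$gain_sd,
                        noise_sd = cf$noise_sd,
                        interhemispheric_miss_rate = cf$interhemispheric_miss_rate,
                        seed = substream_seed(cf$seed, "cohort"))
    setNames(lapply(seq_len(cf$n_subjects), function(s) {
      generate_subject_sc(ctx_gt(ctx), spec, s)
    }), paste0("S", seq_len(cf$n_subjects)))
  })
}

# Tractography misses interhemispheric connections systematically -- the
# same links go undetected in every subject -- so the dropout mask is drawn
# once on the ground truth and each subject's measured SC is generated from
# the degraded core (with the same per-subject gain and noise substreams as
# the intact cohort, preserving subject identity across the two versions).
ctx_degraded_sc <- function(ctx) {
  ctx_get(ctx, "degraded_sc", function() {
    cf <- ctx$config
    dgt <- degrade_sc(ctx_gt(ctx), cf$interhemispheric_miss_rate,
                      seed = substream_seed(cf$seed, "degrade"))
    spec <- cohort_spec(cf$n_subjects, gain_sd = cf$gain_sd,
                        noise_sd = cf$noise_sd,
                        interhemispheric_miss_rate = cf$interhemispheric_miss_rate,
                        seed = substream_seed(cf$seed, "cohort"))
    setNames(lapply(seq_len(cf$n_subjects), function(s) {
      generate_subject_sc(dgt, spec, s)
    }), paste0("S", seq_len(cf$n_subjects)))
  })
}

ctx_empirical_bold <- function(ctx) {
  ctx_get(ctx, "empirical_bold", function() {
    cf <- ctx$config
    lapply(setNames(nm = names(ctx_subject_sc(ctx))), function(s) {
      cfg <- make_model_config(cf, cf$empirical_model, list("empirical", s))
      simulate_bold(ctx_subject_sc(ctx)[[s]], cfg, n_samples = cf$n_samples,
                    tr = cf$tr)
    })
  })
}

ctx_empirical_bold_gsr <- function(ctx) {
  ctx_get(ctx, "empirical_bold_gsr", function() {
    lapply(ctx_empirical_bold(ctx), global_signal_regression)
  })
}

# features x subjects matrix of vectorized empirical cFC
ctx_emp_cfc <- function(ctx, gsr = TRUE) {
  key <- if (gsr) "emp_cfc" else "emp_cfc_nogsr"
  ctx_get(ctx, key, function() {
    runs <- if (gsr) ctx_empirical_bold_gsr(ctx) else ctx_empirical_bold(ctx)
    vapply(runs, function(b) {
      as.numeric(vectorize_upper(pearson_fc(b), ctx_atlas(ctx)))
    }, numeric(choose(ctx$config$n_regions, 2)))
  })
}

ctx_sim_fc <- function(ctx) {
  ctx_get(ctx, "sim_fc", function() {
    cf <- ctx$config
    sc <- ctx_degraded_sc(ctx)
    setNames(lapply(cf$models, function(mod) {
      vapply(names(sc), function(s) {
        cfg <- make_model_config(cf, mod, list("sim", mod, s))
        as.numeric(simulate_fc(mod, sc[[s]], config = cfg,
                               n_samples = cf$n_samples, tr = cf$tr))
      }, numeric(choose(cf$n_regions, 2)))
    }), cf$models)
  })
}

summarize_bsvd <- function(b, keep = 5) {
  k <- min(keep, length(b$bootstrap_fraction_mean))
  list(reproducible_dim = b$reproducible_dim,
       fraction_mean = round(b$bootstrap_fraction_mean[seq_len(k)], 6),
       fraction_sd = round(b$bootstrap_fraction_sd[seq_len(k)], 6),
       variance_fractions = round(b$variance_fractions[seq_len(k)], 6),
       B = b$B, alpha = b$alpha)
}

#' Run one named experiment on the synthetic cohort
#'
#' Each tag reproduces one of the pipeline's analyses: bootstrap SVD of SC,
#' Pearson/mutual-information/3-way/BOLD patterns (`d1_*`), the no-GSR
#' control (`d2_nogsr`), the three permutation controls
#' (`d5_permutations`), simulated-only and pooled analyses (`d6_simulated`,
#' `d7_pooled`), the intrahemispheric restriction (`d8_intrahemispheric`),
#' residual FC (`d9_residual`), the average-subject homotopic manipulation
#' (`d10_average_subject`) and windowed dynamic FC (`d11_dynamic`).
#'
#' @param name An [experiment_tags()] tag.
#' @param config An [experiment_config()].
#' @param context Optional shared [build_experiment_context()]; built on the
#'   fly otherwise.
#' @return A report list (class `scfc_report`) with the experiment name, data
#'   dimensions, reproducible dimension and per-dimension variance fractions
#'   (bootstrap mean and sd), plus tag-specific summaries. Fully reproducible
#'   from `(config, seed)`.
#' @export
run_experiment <- function(name, config = experiment_config(),
                           context = NULL) {
  name <- match.arg(name, experiment_tags())
  ctx <- context %||% build_experiment_context(config)
  cf <- ctx$config
  atlas <- ctx_atlas(ctx)
  bseed <- substream_seed(cf$seed, "bsvd", name)
  npairs <- choose(cf$n_regions, 2)
  report <- switch(name,
    d1_sc = {
      X <- vapply(ctx_degraded_sc(ctx), function(s) {
        as.numeric(vectorize_upper(s$weights, atlas))
      }, numeric(npairs))
      b <- bootstrap_svd(data_matrix(X, colnames(X), "sc"), B = cf$B,
                         alpha = cf$alpha, seed = bseed)
      c(list(measure = "SC", n_features = npairs, n_columns = ncol(X)),
        summarize_bsvd(b))
    },
    d1_cfc = {
      X <- ctx_emp_cfc(ctx)
      b <- bootstrap_svd(data_matrix(X, colnames(X)), B = cf$B,
                         alpha = cf$alpha, seed = bseed)
      c(list(measure = "cFC", n_features = npairs, n_columns = ncol(X)),
        summarize_bsvd(b))
    },
    d1_mfc = {
      X <- vapply(ctx_empirical_bold_gsr(ctx), function(b) {
        as.numeric(mi_fc(b, k = cf$k))
      }, numeric(npairs))
      b <- bootstrap_svd(data_matrix(X, colnames(X)), B = cf$B,
                         alpha = cf$alpha, seed = bseed)
      c(list(measure = "mFC", n_features = npairs, n_columns = ncol(X)),
        summarize_bsvd(b))
    },
    d1_ct3 = {
      ntri <- choose(cf$n_regions, 3)
      X <- vapply(ctx_empirical_bold_gsr(ctx), function(b) {
        as.numeric(ct3(b, k = cf$k, allow_large = TRUE))
      }, numeric(ntri))
      b <- bootstrap_svd(data_matrix(X, colnames(X)), B = cf$B,
                         alpha = cf$alpha, seed = bseed)
      c(list(measure = "CT3", n_features = ntri, n_columns = ncol(X)),
        summarize_bsvd(b))
    },
    d1_bold = {
      dm <- bold_to_datamatrix(ctx_empirical_bold_gsr(ctx))
      b <- bootstrap_svd(dm, B = cf$B, alpha = cf$alpha, seed = bseed)
      c(list(measure = "BOLD", n_features = nrow(dm$X),
             n_columns = ncol(dm$X)), summarize_bsvd(b))
    },
    d2_nogsr = {
      X <- ctx_emp_cfc(ctx, gsr = FALSE)
      b <- bootstrap_svd(data_matrix(X, colnames(X)), B = cf$B,
                         alpha = cf$alpha, seed = bseed)
      c(list(measure = "cFC_noGSR", n_features = npairs, n_columns = ncol(X)),
        summarize_bsvd(b))
    },
    d5_permutations = {
      mats <- lapply(ctx_empirical_bold_gsr(ctx), pearson_fc)
      modes <- c("links", "regions", "within_hemisphere")
      per_mode <- lapply(setNames(nm = modes), function(mode) {
        dm <- permute_dataset(mats, atlas, mode = mode,
                              seed = substream_seed(cf$seed, "perm", mode))
        b <- bootstrap_svd(dm, B = cf$B, alpha = cf$alpha, seed = bseed)
        summarize_bsvd(b, keep = 3)
      })
      list(measure = "cFC_permuted", n_features = npairs,
           n_columns = cf$n_subjects, modes = per_mode)
    },
    d6_simulated = {
      dm <- pool_datasets(ctx_sim_fc(ctx))
      b <- bootstrap_svd(dm, B = cf$B, alpha = cf$alpha, seed = bseed)
      c(list(measure = "simulated_cFC", n_features = npairs,
             n_columns = ncol(dm$X)), summarize_bsvd(b))
    },
    d7_pooled = {
      dm <- pool_datasets(c(list(empirical = ctx_emp_cfc(ctx)),
                            ctx_sim_fc(ctx)))
      b <- bootstrap_svd(dm, B = cf$B, alpha = cf$alpha, seed = bseed)
      gt_vec <- as.numeric(vectorize_upper(ctx_gt(ctx)$weights, atlas))
      r_sc <- cor(b$left_vectors[, 1], gt_vec)
      c(list(measure = "pooled_cFC", n_features = npairs,
             n_columns = ncol(dm$X),
             cor_dim1_with_true_sc = r_sc), summarize_bsvd(b))
    },
    d8_intrahemispheric = {
      dm <- pool_datasets(c(list(empirical = ctx_emp_cfc(ctx)),
                            ctx_sim_fc(ctx)))
      idx <- pair_index(cf$n_regions)
      keep <- atlas$hemisphere[idx[, 1]] == atlas$hemisphere[idx[, 2]]
      sub <- data_matrix(dm$X[keep, , drop = FALSE], dm$subject, dm$source)
      b <- bootstrap_svd(sub, B = cf$B, alpha = cf$alpha, seed = bseed)
      c(list(measure = "pooled_cFC_intrahemispheric", n_features = sum(keep),
             n_columns = ncol(sub$X)), summarize_bsvd(b))
    },
    d9_residual = {
      dm <- residual_fc(ctx_emp_cfc(ctx), ctx_sim_fc(ctx))
      b <- bootstrap_svd(dm, B = cf$B, alpha = cf$alpha, seed = bseed)
      idx <- pair_index(cf$n_regions)
      inter <- atlas$hemisphere[idx[, 1]] != atlas$hemisphere[idx[, 2]]
      u1 <- b$left_vectors[, 1]
      c(list(measure = "residual_cFC", n_features = npairs,
             n_columns = ncol(dm$X),
             interhemispheric_share_dim1 = sum(u1[inter]^2),
             interhemispheric_share_features = mean(inter)),
        summarize_bsvd(b))
    },
    d10_average_subject = {
      avg <- average_sc(ctx_degraded_sc(ctx))
      manip <- set_homotopic_weight(avg, cf$homotopic_value)
      emp_avg <- rowMeans(ctx_emp_cfc(ctx))
      sim_on <- function(sc, tag) {
        vapply(cf$models, function(mod) {
          cfg <- make_model_config(cf, mod, list("avg", tag, mod))
          as.numeric(simulate_fc(mod, sc, config = cfg,
                                 n_samples = cf$n_samples, tr = cf$tr))
        }, numeric(npairs))
      }
      frac12 <- function(sc, tag) {
        X <- cbind(empirical = emp_avg, sim_on(sc, tag))
        f <- svd_variance(X)$variance_fractions
        list(fraction_1 = f[1], fraction_2 = f[2])
      }
      list(measure = "average_subject_cFC", n_features = npairs,
           n_columns = length(cf$models) + 1,
           original = frac12(avg, "orig"),
           manipulated = frac12(manip, "manip"),
           homotopic_value = cf$homotopic_value)
    },
    d11_dynamic = {
      wins <- cf$windows[cf$n_samples %% cf$windows == 0]
      runs <- ctx_empirical_bold_gsr(ctx)
      per_window <- lapply(setNames(nm = as.character(wins)), function(w) {
        w <- as.integer(w)
        X <- vapply(runs, function(b) as.numeric(dynamic_fc(b, w)),
                    numeric((cf$n_samples %/% w) * npairs))
        b <- bootstrap_svd(data_matrix(X, colnames(X)), B = cf$B,
                           alpha = cf$alpha, seed = bseed)
        c(list(n_windows = cf$n_samples %/% w,
               window_seconds = w * cf$tr,
               n_features = nrow(X)), summarize_bsvd(b, keep = 3))
      })
      list(measure = "dynFC", n_columns = cf$n_subjects,
           windows = per_window)
    }
  )
  structure(c(list(experiment = name, seed = cf$seed,
                   n_regions = cf$n_regions, n_subjects = cf$n_subjects),
              report),
            class = c("scfc_report", "list"))
}

#' @export
print.scfc_report <- function(x, ...) {
  cat("experiment:", x$experiment, "\n")
  if (!is.null(x$reproducible_dim)) {
    cat(sprintf("  d = %d; dim-1 variance %.1f%% +/- %.1f%%\n",
                x$reproducible_dim, 100 * x$fraction_mean[1],
                100 * x$fraction_sd[1]))
  }
  invisible(x)
}
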