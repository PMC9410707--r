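#' Run the full synthetic-cohort pipeline
#'
#' Samples a cohort, forward-simulates per-electrode spectra, decomposes each
#' spectrum into periodic and aperiodic components, extracts the alpha/aperiodic
#' parameter set, aggregates over the electrode cluster with the fit-quality
#' fallback, and applies the subject-level exclusion rules (no detectable
#' alpha peak; single-pass 3-sd outlier screen across all extracted
#' parameters).
#'
#' @param preset A [generative_preset].
#' @param n Number of subjects.
#' @param seed Integer seed controlling cohort sampling and spectrum noise.
#' @param n_electrodes Electrodes per subject (default from the preset).
#' @param settings [spectral_settings()] for the decomposition.
#' @param outlier_k Outlier threshold in sd (default 3).
#' @return A list with `cohort` (the sampled [sample_cohort()] table) and
#'   `metrics`: one row per subject with covariates, the nine aggregated
#'   parameters, `n_electrodes_used`, `excluded` and `reason`.
#' @export
run_cohort_pipeline <- function(preset, n, seed = 1L,
                                n_electrodes = preset$n_electrodes,
                                settings = spectral_settings(),
                                outlier_k = 3) {
  cohort <- sample_cohort(preset, n, seed)
  theta <- cohort_latents(cohort)
  set.seed(seed + 1L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    per_el <- vector("list", n_electrodes)
    for (e in seq_len(n_electrodes)) {
      sp <- generate_spectrum(theta[i, ], preset)
      fit <- parameterize_spectrum(sp, settings)
      per_el[[e]] <- compute_metrics(sp, fit)
    }
    rows[[i]] <- aggregate_cluster(do.call(rbind, per_el),
                                   min_r2 = settings$min_r_squared)
  }
  metrics <- do.call(rbind, rows)
  metrics <- cbind(subject_id = cohort$subject_id, metrics)

  ok <- !metrics$excluded
  if (sum(ok) >= 3L) {
    out_mask <- flag_outliers(metrics[ok, , drop = FALSE], k = outlier_k)
    idx <- which(ok)[out_mask]
    metrics$excluded[idx] <- TRUE
    metrics$reason[idx] <- "outlier"
  }
  covars <- cohort[, c("subject_id", "age", "gender", "ehi", "site",
                       "diagnosis", "fa_left", "fa_right", "icv",
                       "flanker_score")]
  list(cohort = cohort,
       metrics = merge(covars, metrics, by = "subject_id", sort = FALSE))
}

pipeline_outcomes <- c("iaf", "total_individualized", "relative_individualized",
                       "adjusted_individualized", "aperiodic_intercept",
                       "aperiodic_exponent")

#' Standardized maturation coefficients from a pipeline metric table
#'
#' Reproduces the study's standardized coefficient estimates on a simulated
#' cohort: for each of the six individualized outcomes, the outcome and age are
#' Gelman-scaled (0.5 sd) and `outcome ~ age + gender` is fitted (gender as an
#' untransformed 0/1 dummy, 1 = female); the anatomical model regresses
#' aperiodic-adjusted individualized alpha power on left-tract fractional
#' anisotropy, total intracranial volume, age and gender (all numerics
#' Gelman-scaled); the behavioral model regresses it on the attention-task
#' score, age and gender with plain z-scoring. Excluded subjects are dropped
#' first.
#'
#' @param metrics The `metrics` table from [run_cohort_pipeline()].
#' @param interval_level Interval coverage for the reported bounds.
#' @param backend Passed to [fit_outcome_model()].
#' @return A list with `age` and `gender` (named vectors of standardized
#'   coefficients over the six outcomes), `fa` and `score` (scalars), and
#'   `models` (the full coefficient tables).
#' @export
maturation_coefficients <- function(metrics, interval_level = 0.9917,
                                    backend = "ols") {
  d <- metrics[!metrics$excluded, , drop = FALSE]
  d <- d[stats::complete.cases(d[pipeline_outcomes]), , drop = FALSE]

  ds <- d
  ds$age <- gelman_scale(d$age)
  for (oc in pipeline_outcomes) ds[[oc]] <- gelman_scale(d[[oc]])
  models <- list()
  age_b <- gender_b <- stats::setNames(numeric(length(pipeline_outcomes)),
                                       pipeline_outcomes)
  for (oc in pipeline_outcomes) {
    m <- fit_outcome_model(oc, c("age", "gender"), ds, backend = backend,
                           interval_level = interval_level)
    models[[oc]] <- m
    age_b[oc] <- m$estimate[m$term == "age"]
    gender_b[oc] <- m$estimate[m$term == "gender"]
  }

  da <- d
  for (v in c("adjusted_individualized", "fa_left", "icv", "age")) {
    da[[v]] <- gelman_scale(d[[v]])
  }
  m_fa <- fit_outcome_model("adjusted_individualized",
                            c("fa_left", "icv", "age", "gender"), da,
                            backend = backend, interval_level = interval_level)
  models$fa <- m_fa

  dz <- d
  for (v in c("adjusted_individualized", "flanker_score", "age")) {
    dz[[v]] <- as.numeric(scale(d[[v]]))
  }
  m_sc <- fit_outcome_model("adjusted_individualized",
                            c("flanker_score", "age", "gender"), dz,
                            backend = backend, interval_level = interval_level)
  models$score <- m_sc

  list(age = age_b, gender = gender_b,
       fa = m_fa$estimate[m_fa$term == "fa_left"],
       score = m_sc$estimate[m_sc$term == "flanker_score"],
       models = models)
}
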