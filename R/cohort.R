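#' Sample a synthetic cohort
#'
#' Draws `n` subjects: demographic covariates (age, gender, handedness, site,
#' diagnosis), synthetic anatomical (fractional anisotropy of the left/right
#' thalamic radiation, total intracranial volume) and behavioral (standardized
#' attention-task score) covariates, and per-subject latent spectral parameters
#' following `param_means + effect_matrix %*% covariates + correlated
#' residuals` scaled to `param_sds`. Residual spread is shrunk so each latent
#' parameter's total standard deviation equals its configured `param_sds`
#' entry, making effect-matrix entries latent-covariate correlations.
#'
#' Latent draws are clipped to their physical support: the individual alpha
#' frequency to `(7 + eps, 14 - eps)` (so the downstream border-rejection rule
#' is not triggered by construction), the alpha width to the peak-width limits,
#' and peak heights to be non-negative.
#'
#' @param preset A [generative_preset].
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; the same seed yields an identical cohort.
#' @return A `cohort_table` data frame with one row per subject: covariates,
#'   gender coded 1 = female, and the latent parameter columns `true_*`.
#' @export
sample_cohort <- function(preset, n, seed = 1L) {
  validate_preset(preset)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  set.seed(seed)

  age <- rnorm(n, preset$age_mean, preset$age_sd)
  bad <- which(age < preset$age_range[1] | age > preset$age_range[2])
  while (length(bad)) {
    age[bad] <- rnorm(length(bad), preset$age_mean, preset$age_sd)
    bad <- bad[age[bad] < preset$age_range[1] | age[bad] > preset$age_range[2]]
  }
  gender <- rbinom(n, 1L, preset$p_female)
  ehi <- pmin(pmax(round(rnorm(n, 60, 40)), -100L), 100L)
  site <- sample(c("RU", "CBIC", "SI"), n, replace = TRUE,
                 prob = c(0.5, 0.35, 0.15))
  diagnosis <- sample(names(preset$diagnosis_probs), n, replace = TRUE,
                      prob = preset$diagnosis_probs)

  age_z <- as.numeric(scale(age))
  gender_z <- if (stats::sd(gender) > 0) as.numeric(scale(gender)) else gender * 0

  # fractional anisotropy of the two thalamic radiations: shared component with
  # an age loading plus a small side-specific part (left/right nearly collinear)
  lam <- preset$fa_age_loading
  eta <- 0.22
  u <- rnorm(n); e1 <- rnorm(n); e2 <- rnorm(n)
  common <- sqrt(max(1 - lam^2 - eta^2, 0)) * u
  fa_left_z <- lam * age_z + common + eta * e1
  fa_right_z <- lam * age_z + common + eta * e2
  rho <- preset$score_age_loading
  score_z <- rho * age_z + sqrt(1 - rho^2) * rnorm(n)
  icv <- rnorm(n, 1450, 120) + 60 * (1 - gender)

  X <- cbind(age = age_z, gender = gender_z, fa = fa_left_z, score = score_z)
  E <- preset$effect_matrix
  Sx <- stats::cov(X)
  vk <- rowSums((E %*% Sx) * E)
  if (any(vk > 1 + 1e-8)) {
    stop("effect_matrix rows explain more than the configured latent variance; ",
         "reduce the effects or increase param_sds", call. = FALSE)
  }
  ck <- sqrt(pmax(1 - vk, 0))
  Z <- matrix(rnorm(n * 6), n, 6) %*% chol(preset$residual_corr)
  theta_std <- X %*% t(E) + Z %*% diag(ck)
  theta <- sweep(sweep(theta_std, 2, preset$param_sds, `*`), 2,
                 preset$param_means, `+`)
  colnames(theta) <- latent_names

  eps <- preset$iaf_clip_eps
  theta[, "iaf"] <- pmin(pmax(theta[, "iaf"], 7 + eps), 14 - eps)
  theta[, "alpha_width"] <- pmin(pmax(theta[, "alpha_width"], 0.55), 11.9)
  theta[, "alpha_level"] <- pmax(theta[, "alpha_level"], 0.05)
  theta[, "theta_level"] <- pmax(theta[, "theta_level"], 0)

  out <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = age, gender = gender, ehi = ehi, site = site, diagnosis = diagnosis,
    fa_left = 0.45 + 0.03 * fa_left_z,
    fa_right = 0.45 + 0.03 * fa_right_z,
    icv = icv,
    flanker_score = score_z,
    stringsAsFactors = FALSE
  )
  truth <- as.data.frame(theta)
  names(truth) <- paste0("true_", latent_names)
  out <- cbind(out, truth)
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "preset") <- preset
  out
}

#' Latent parameter matrix of a cohort
#' @param cohort A `cohort_table` from [sample_cohort()].
#' @return An n x 6 matrix of latent parameters (columns [latent-parameters]).
#' @export
cohort_latents <- function(cohort) {
  m <- as.matrix(cohort[, paste0("true_", latent_names)])
  colnames(m) <- latent_names
  m
}
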