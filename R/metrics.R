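#' Detect the individual alpha frequency (IAF)
#'
#' Returns the frequency of the maximum power bin within the search window.
#' If the argmax falls on the window border the peak is considered undetected
#' (`NA`): a border maximum indicates a monotone spectrum rather than a true
#' alpha peak. Ties are broken toward the lower frequency and the IAF is
#' reported at grid resolution (no interpolation).
#'
#' @param spectrum A [power_spectrum].
#' @param lo,hi Search window in Hz (defaults 7 and 14).
#' @return IAF in Hz, or `NA_real_` if no peak was detected.
#' @export
detect_iaf <- function(spectrum, lo = 7, hi = 14) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  eps <- 1e-9
  if (min(spectrum$freqs) > lo + eps || max(spectrum$freqs) < hi - eps) {
    stop("frequency grid does not cover the IAF search window", call. = FALSE)
  }
  idx <- band_index(spectrum$freqs, c(lo, hi))
  f <- spectrum$freqs[idx][which.max(spectrum$power[idx])]
  if (abs(f - lo) < eps || abs(f - hi) < eps) return(NA_real_)
  f
}

#' Band-averaged power
#'
#' Arithmetic mean of power over all bins within the band, endpoints
#' inclusive. With `scale = "linear"` log10 power is back-transformed first and
#' the mean of linear power is returned.
#'
#' @param spectrum A [power_spectrum] on the log10 scale.
#' @param band `c(lo, hi)` in Hz.
#' @param scale `"log"` (mean log10 power) or `"linear"` (mean linear power).
#' @return A single numeric value.
#' @export
band_average <- function(spectrum, band, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  stopifnot(inherits(spectrum, "power_spectrum"))
  sp <- spectrum_rescale(spectrum, "log")
  idx <- band_index(sp$freqs, band)
  if (scale == "log") mean(sp$power[idx]) else mean(10^sp$power[idx])
}

metric_names <- c("iaf", "total_canonical", "total_individualized",
                  "relative_canonical", "relative_individualized",
                  "adjusted_canonical", "adjusted_individualized",
                  "aperiodic_intercept", "aperiodic_exponent")

#' Extract the alpha/aperiodic parameter set for one spectrum
#'
#' Computes the nine per-electrode parameters: IAF; total (mean log10 power of
#' the data spectrum) alpha power in the canonical 8-13 Hz band and in the
#' individualized band `[IAF - 4, IAF + 2]` Hz; relative alpha power (linear
#' band power divided by mean linear power across the full 2-40 Hz range);
#' aperiodic-adjusted alpha power (mean log10 periodic power, i.e. after
#' subtracting the fitted aperiodic curve) for both bands; and the fitted
#' aperiodic intercept and exponent. When no IAF is detected the three
#' individualized measures are `NA` and all other fields are still produced.
#'
#' @param spectrum A [power_spectrum].
#' @param fit The [parameterize_spectrum()] fit of that spectrum.
#' @param canonical_band Fixed alpha band (default `c(8, 13)` Hz).
#' @param iaf_window IAF search window (default `c(7, 14)` Hz).
#' @return A one-row data frame with the nine parameters plus `r_squared`.
#' @export
compute_metrics <- function(spectrum, fit, canonical_band = c(8, 13),
                            iaf_window = c(7, 14)) {
  stopifnot(inherits(spectrum, "power_spectrum"), inherits(fit, "spectral_fit"))
  sp <- spectrum_rescale(spectrum, "log")
  full_range <- fit$settings$freq_range
  periodic <- periodic_spectrum(sp, fit)
  iaf <- detect_iaf(sp, iaf_window[1], iaf_window[2])
  denom <- band_average(sp, full_range, "linear")

  out <- data.frame(
    iaf = iaf,
    total_canonical = band_average(sp, canonical_band, "log"),
    total_individualized = NA_real_,
    relative_canonical = band_average(sp, canonical_band, "linear") / denom,
    relative_individualized = NA_real_,
    adjusted_canonical = band_average(periodic, canonical_band, "log"),
    adjusted_individualized = NA_real_,
    aperiodic_intercept = unname(fit$aperiodic[1]),
    aperiodic_exponent = unname(fit$aperiodic[2]),
    r_squared = fit$r_squared
  )
  if (!is.na(iaf)) {
    band <- c(iaf - 4, iaf + 2)
    band[1] <- max(band[1], full_range[1])
    band[2] <- min(band[2], full_range[2])
    out$total_individualized <- band_average(sp, band, "log")
    out$relative_individualized <- band_average(sp, band, "linear") / denom
    out$adjusted_individualized <- band_average(periodic, band, "log")
  }
  out
}

#' Aggregate per-electrode metrics over the posterior cluster
#'
#' Electrodes whose spectral fit quality is at or below `min_r2` are dropped
#' and the remaining electrodes' parameters are averaged parameter-wise. If
#' every electrode fails the gate the subject is flagged (`all_poor_fit`) and
#' all electrodes are averaged rather than silently discarded; poor model fit
#' alone never excludes a subject. A subject with no detectable IAF on any
#' electrode is excluded with reason `"no_iaf"`; individualized measures are
#' averaged over the electrodes with a detected peak.
#'
#' @param metrics A data frame of per-electrode rows as returned by
#'   [compute_metrics()] (one row per electrode, including `r_squared`).
#' @param min_r2 Fit-quality gate (default 0.90).
#' @return A one-row data frame: the nine averaged parameters plus
#'   `n_electrodes_used`, `all_poor_fit`, `excluded` and `reason`.
#' @export
aggregate_cluster <- function(metrics, min_r2 = 0.90) {
  if (!is.data.frame(metrics) || nrow(metrics) < 1L) {
    stop("need metrics for at least one electrode", call. = FALSE)
  }
  ok <- metrics$r_squared > min_r2
  all_poor <- !any(ok)
  use <- if (all_poor) metrics else metrics[ok, , drop = FALSE]
  agg <- as.data.frame(lapply(use[metric_names], function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }))
  agg$n_electrodes_used <- nrow(use)
  agg$all_poor_fit <- all_poor
  if (is.na(agg$iaf)) {
    agg$excluded <- TRUE
    agg$reason <- "no_iaf"
  } else {
    agg$excluded <- FALSE
    agg$reason <- NA_character_
  }
  agg
}

#' Flag multivariate outliers in a cohort metric table
#'
#' Single-pass rule: a subject is flagged when any parameter lies beyond
#' `mean +/- k * sd` of the sample for that parameter (no iterative
#' re-trimming). Zero-variance columns are skipped with a warning.
#'
#' @param metrics Data frame of subject-level metrics (numeric columns are
#'   used; `NA`s do not flag a subject).
#' @param k Threshold in standard deviations (default 3).
#' @param columns Columns to screen (default: the nine extracted parameters
#'   present in the table).
#' @return Logical vector, `TRUE` for subjects to exclude.
#' @export
flag_outliers <- function(metrics, k = 3, columns = intersect(metric_names, names(metrics))) {
  if (nrow(metrics) < 3L) stop("need at least 3 subjects", call. = FALSE)
  out <- rep(FALSE, nrow(metrics))
  for (cl in columns) {
    x <- metrics[[cl]]
    if (!is.numeric(x)) next
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("column '%s' has zero variance; skipped", cl), call. = FALSE)
      next
    }
    m <- mean(x, na.rm = TRUE)
    out <- out | (!is.na(x) & abs(x - m) > k * s)
  }
  out
}
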