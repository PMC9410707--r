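#' Settings for spectral parameterization
#'
#' Defaults follow the published algorithm settings used throughout:
#' fit range 2-40 Hz, peak width limits `[0.5, 12]` Hz (full width; Gaussian sd
#' limits are half of these), minimum peak height 0, peak threshold 2 sd of the
#' current flattened residual, aperiodic mode fixed (no knee). "Unlimited"
#' peaks is realized as a practical safety cap (`max_n_peaks`, default 12)
#' together with the threshold stopping rule. Fits with `r_squared <=
#' min_r_squared` are flagged as poor.
#'
#' @param freq_range Fit range in Hz.
#' @param peak_width_limits Full-width limits for peaks in Hz.
#' @param max_n_peaks Safety cap on the number of extracted peaks.
#' @param min_peak_height Minimum absolute peak height, log10 units.
#' @param peak_threshold Relative threshold in sd of the flattened residual.
#' @param ap_percentile Percentile of the floored residual used to mask peak
#'   regions in the robust aperiodic fit (default 2.5).
#' @param min_r_squared Fit-quality gate.
#' @param n_cycles Maximum number of flatten/extract/background-refit cycles
#'   (the loop stops early once the background parameters settle to 1e-3);
#'   repeated cycles remove the residual background bias that broad peaks
#'   leave in a single pass.
#' @return A list of settings.
#' @export
spectral_settings <- function(freq_range = c(2, 40),
                              peak_width_limits = c(0.5, 12),
                              max_n_peaks = 12L,
                              min_peak_height = 0,
                              peak_threshold = 2,
                              ap_percentile = 2.5,
                              min_r_squared = 0.90,
                              n_cycles = 5L) {
  list(freq_range = freq_range, peak_width_limits = peak_width_limits,
       max_n_peaks = as.integer(max_n_peaks),
       min_peak_height = min_peak_height, peak_threshold = peak_threshold,
       ap_percentile = ap_percentile, min_r_squared = min_r_squared,
       n_cycles = as.integer(n_cycles))
}

# exact linear least squares of power ~ offset - exponent * log10(f)
ap_fit_simple <- function(freqs, power) {
  fit <- stats::.lm.fit(cbind(1, -log10(freqs)), power)
  c(offset = fit$coefficients[1], exponent = fit$coefficients[2])
}

# two-pass robust fit: initial fit, floor negative residuals at zero, mask out
# points whose floored residual exceeds the low percentile (peak regions lie
# above the background, so the kept points are the spectral minima), refit
ap_fit_robust <- function(freqs, power, ap_percentile = 2.5) {
  if (length(freqs) < 3L) stop("need at least 3 usable bins", call. = FALSE)
  ap0 <- ap_fit_simple(freqs, power)
  flat <- power - aperiodic_curve(freqs, ap0[1], ap0[2])
  flat[flat < 0] <- 0
  thr <- stats::quantile(flat, ap_percentile / 100, names = FALSE)
  mask <- flat <= thr
  if (sum(mask) < 3L) stop("fewer than 3 bins left for the aperiodic refit", call. = FALSE)
  ap_fit_simple(freqs[mask], power[mask])
}

#' Robust fit of the aperiodic background
#'
#' Fits `b - chi * log10(F)` in two passes so that oscillatory peak regions do
#' not bias the background estimate: after an initial least-squares fit,
#' residuals are floored at zero and only points at or below the low-percentile
#' threshold of the floored residual (i.e. points not above the initial curve)
#' are kept for the final fit.
#'
#' @param spectrum A [power_spectrum] on the log10 scale covering the fit range.
#' @param ap_percentile Masking percentile (default 2.5).
#' @return Named vector `c(offset, exponent)`.
#' @export
fit_aperiodic_robust <- function(spectrum, ap_percentile = 2.5) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sp <- spectrum_rescale(spectrum, "log")
  ap_fit_robust(sp$freqs, sp$power, ap_percentile)
}

# iterative peak guessing on a flattened spectrum, following the reference
# procedure: take the maximum, stop at the threshold, guess the width from the
# half-height crossing of the shorter side, subtract, repeat; then drop guesses
# within one guessed sd of a range edge and overlapping guesses.
guess_peaks <- function(freqs, flat, settings) {
  df <- freqs[2] - freqs[1]
  sd_lim <- settings$peak_width_limits / 2
  guesses <- NULL
  flat_iter <- flat
  for (i in seq_len(settings$max_n_peaks)) {
    i_max <- which.max(flat_iter)
    h <- flat_iter[i_max]
    if (h <= settings$peak_threshold * stats::sd(flat_iter)) break
    if (h <= settings$min_peak_height) break
    cf <- freqs[i_max]
    half <- h / 2
    ri <- which(flat_iter[seq(i_max, length(freqs))] <= half)
    li <- which(flat_iter[seq(i_max, 1L)] <= half)
    right <- if (length(ri)) ri[1] - 1L else NA_integer_
    left <- if (length(li)) li[1] - 1L else NA_integer_
    short_side <- suppressWarnings(min(right, left, na.rm = TRUE))
    if (!is.finite(short_side) || short_side < 1L) short_side <- 1L
    fwhm <- 2 * short_side * df
    gsd <- fwhm / (2 * sqrt(2 * log(2)))
    gsd <- min(max(gsd, sd_lim[1]), sd_lim[2])
    guesses <- rbind(guesses, c(cf, h, gsd))
    flat_iter <- flat_iter - gaussian_curve(freqs, cf, h, gsd)
  }
  if (is.null(guesses)) return(matrix(numeric(0), 0, 3))
  # drop peaks whose center is within one guessed sd of a range edge
  keep <- (guesses[, 1] - freqs[1]) > guesses[, 3] &
          (freqs[length(freqs)] - guesses[, 1]) > guesses[, 3]
  guesses <- guesses[keep, , drop = FALSE]
  # among overlapping guesses (centers closer than 0.75 * summed sds) keep the taller
  if (nrow(guesses) > 1L) {
    ord <- order(guesses[, 1])
    g <- guesses[ord, , drop = FALSE]
    drop <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(g) - 1L)) {
      if (g[i + 1L, 1] - g[i, 1] < 0.75 * (g[i, 3] + g[i + 1L, 3])) {
        if (g[i, 2] < g[i + 1L, 2]) drop[i] <- TRUE else drop[i + 1L] <- TRUE
      }
    }
    guesses <- g[!drop, , drop = FALSE]
  }
  guesses
}

# joint bounded least-squares refit with analytic gradients; centers stay
# within 1.5 guessed sd of their guess, widths within the limits. When `ap` is
# supplied the aperiodic parameters are refined jointly with the peaks
# (equivalent to alternating peak/background refits, run to convergence).
refit_peaks <- function(freqs, flat, guesses, settings, ap = NULL) {
  k <- nrow(guesses)
  if (k == 0L) {
    if (is.null(ap)) return(guesses)
    return(list(peaks = guesses, ap = ap_fit_simple(freqs, flat)))
  }
  sd_lim <- settings$peak_width_limits / 2
  p0 <- as.numeric(t(guesses))
  lower <- as.numeric(t(cbind(guesses[, 1] - 1.5 * guesses[, 3], 0, sd_lim[1])))
  upper <- as.numeric(t(cbind(guesses[, 1] + 1.5 * guesses[, 3], Inf, sd_lim[2])))
  with_ap <- !is.null(ap)
  if (with_ap) {
    p0 <- c(ap, p0)
    lower <- c(-Inf, -Inf, lower)
    upper <- c(Inf, Inf, upper)
  }
  lf <- log10(freqs)
  cache_p <- NULL
  cache_val <- NULL
  parts_of <- function(p) {
    q <- if (with_ap) p[-(1:2)] else p
    P <- matrix(q, 3L, k)                       # rows: cf, h, w
    D <- outer(freqs, P[1L, ], `-`)
    E <- exp(-D^2 / (2 * rep(P[3L, ]^2, each = length(freqs))))
    model <- as.numeric(E %*% P[2L, ])
    if (with_ap) model <- model + p[1] - p[2] * lf
    list(P = P, D = D, E = E, model = model)
  }
  parts <- function(p) {      # optim calls fn and gr at the same point
    if (!identical(p, cache_p)) {
      cache_p <<- p
      cache_val <<- parts_of(p)
    }
    cache_val
  }
  fn <- function(p) sum((flat - parts(p)$model)^2)
  gr <- function(p) {
    pp <- parts(p)
    r <- pp$model - flat
    RE <- r * pp$E
    g <- rbind(2 * pp$P[2L, ] * colSums(RE * pp$D) / pp$P[3L, ]^2,
               2 * colSums(RE),
               2 * pp$P[2L, ] * colSums(RE * pp$D^2) / pp$P[3L, ]^3)
    if (with_ap) c(2 * sum(r), -2 * sum(r * lf), as.numeric(g))
    else as.numeric(g)
  }
  opt <- tryCatch(
    stats::optim(p0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 200L)),
    error = function(e) NULL
  )
  p <- if (is.null(opt)) p0 else opt$par
  if (with_ap) {
    ap_out <- c(offset = p[1], exponent = p[2])
    p <- p[-(1:2)]
  }
  out <- matrix(p, ncol = 3L, byrow = TRUE)
  out <- out[out[, 2] > settings$min_peak_height, , drop = FALSE]
  if (with_ap) list(peaks = out, ap = ap_out) else out
}

#' Extract Gaussian peaks from a flattened spectrum
#'
#' Iteratively locates the maximum of the flattened (background-subtracted)
#' residual, stops when its height falls at or below
#' `max(min_peak_height, peak_threshold * sd(residual))` or when the practical
#' peak cap is reached, guesses each peak's width from its half-height
#' crossings (clipped to the width limits), subtracts the guess and continues;
#' accepted guesses are then refit jointly by least squares. Peaks whose center
#' lies within one guessed sd of a range edge are dropped. An empty result is
#' a valid output.
#'
#' @param flattened A [power_spectrum] containing the flattened residual
#'   (data minus aperiodic curve), log10 units.
#' @param settings A [spectral_settings()] list.
#' @return A data frame with columns `center` (Hz), `height` (log10 units) and
#'   `width` (Gaussian sd, Hz), tallest peaks extracted first.
#' @export
extract_peaks <- function(flattened, settings = spectral_settings()) {
  stopifnot(inherits(flattened, "power_spectrum"))
  g <- guess_peaks(flattened$freqs, flattened$power, settings)
  g <- refit_peaks(flattened$freqs, flattened$power, g, settings)
  out <- data.frame(center = g[, 1], height = g[, 2], width = g[, 3])
  out[order(-out$height), , drop = FALSE]
}

#' Decompose a power spectrum into aperiodic and periodic components
#'
#' Full algorithm: robust aperiodic fit, flattening, iterative Gaussian peak
#' extraction with joint refit, subtraction of the refit peaks from the
#' original spectrum, a final aperiodic fit on the peak-removed spectrum, and
#' reassembly of the model spectrum as final aperiodic curve plus peaks.
#' `r_squared` is the squared Pearson correlation between model and data.
#' The optimizer is deterministic: the same spectrum and settings always give
#' the identical fit.
#'
#' @param spectrum A [power_spectrum] (log10 scale; linear input is rescaled).
#' @param settings A [spectral_settings()] list.
#' @return An object of class `spectral_fit` with elements `aperiodic`
#'   (`c(offset, exponent)`), `peaks` (data frame), `model_spectrum`, `freqs`,
#'   `r_squared`, `mae`, `good_fit` (`r_squared > min_r_squared`) and
#'   `settings`.
#' @export
parameterize_spectrum <- function(spectrum, settings = spectral_settings()) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sp <- spectrum_rescale(spectrum, "log")
  idx <- band_index(sp$freqs, settings$freq_range)
  freqs <- sp$freqs[idx]
  power <- sp$power[idx]

  peak_sum <- function(g) {
    m <- numeric(length(freqs))
    for (j in seq_len(nrow(g))) {
      m <- m + gaussian_curve(freqs, g[j, 1], g[j, 2], g[j, 3])
    }
    m
  }
  # broad peaks bias a single background pass, so flattening and (cheap,
  # guess-level) peak removal are cycled until the background settles; the
  # joint peak refit is then done once against the settled background
  ap <- ap_fit_robust(freqs, power, settings$ap_percentile)
  for (cycle in seq_len(settings$n_cycles)) {
    flat <- power - aperiodic_curve(freqs, ap[1], ap[2])
    g <- guess_peaks(freqs, flat, settings)
    ap_new <- ap_fit_simple(freqs, power - peak_sum(g))
    settled <- max(abs(ap_new - ap)) < 1e-3
    ap <- ap_new
    if (settled) break
  }
  flat <- power - aperiodic_curve(freqs, ap[1], ap[2])
  g <- guess_peaks(freqs, flat, settings)
  full <- refit_peaks(freqs, power, g, settings, ap = ap)
  g <- full$peaks
  ap <- full$ap
  peak_model <- peak_sum(g)
  model <- aperiodic_curve(freqs, ap[1], ap[2]) + peak_model
  r2 <- if (stats::sd(model) == 0 || stats::sd(power) == 0) 0
        else stats::cor(model, power)^2
  peaks <- data.frame(center = g[, 1], height = g[, 2], width = g[, 3])
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  structure(
    list(aperiodic = ap, peaks = peaks, model_spectrum = model, freqs = freqs,
         r_squared = r2, mae = mean(abs(model - power)),
         good_fit = r2 > settings$min_r_squared, settings = settings),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> offset %.3f, exponent %.3f, %d peak(s), R^2 %.4f%s\n",
              x$aperiodic[1], x$aperiodic[2], nrow(x$peaks), x$r_squared,
              if (x$good_fit) "" else " [poor fit]"))
  invisible(x)
}

#' Aperiodic-adjusted (periodic) spectrum
#'
#' Subtracts the final fitted aperiodic curve from the data spectrum, leaving
#' the periodic (oscillatory) signal in log10 units. Together with the
#' aperiodic curve this reconstructs the original data exactly.
#'
#' @param spectrum The [power_spectrum] the fit was produced from.
#' @param fit A [parameterize_spectrum()] result for that spectrum.
#' @return A [power_spectrum] of periodic power, tagged aperiodic-adjusted.
#' @export
periodic_spectrum <- function(spectrum, fit) {
  stopifnot(inherits(spectrum, "power_spectrum"), inherits(fit, "spectral_fit"))
  sp <- spectrum_rescale(spectrum, "log")
  idx <- band_index(sp$freqs, fit$settings$freq_range)
  if (length(idx) != length(fit$freqs) ||
      max(abs(sp$freqs[idx] - fit$freqs)) > 1e-9) {
    stop("fit does not match the spectrum's frequency grid", call. = FALSE)
  }
  out <- power_spectrum(fit$freqs,
                        sp$power[idx] - aperiodic_curve(fit$freqs,
                                                        fit$aperiodic[1],
                                                        fit$aperiodic[2]),
                        "log", sp$n_epochs_used)
  attr(out, "adjusted") <- TRUE
  out
}
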