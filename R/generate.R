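#' Model curves of the generative spectral model
#'
#' `aperiodic_curve` evaluates the 1/f-like background in log10 power units,
#' `offset - exponent * log10(f)` (fixed mode, no knee). `gaussian_curve`
#' evaluates a Gaussian peak `height * exp(-(f - center)^2 / (2 * width^2))`.
#'
#' @param freqs Frequencies in Hz.
#' @param offset,exponent Aperiodic intercept (log10 units) and exponent.
#' @param center,height,width Peak center (Hz), height (log10 units above the
#'   background) and Gaussian sd (Hz).
#' @return Numeric vector of log10 power values.
#' @export
aperiodic_curve <- function(freqs, offset, exponent) {
  offset - exponent * log10(freqs)
}

#' @rdname aperiodic_curve
#' @export
gaussian_curve <- function(freqs, center, height, width) {
  height * exp(-(freqs - center)^2 / (2 * width^2))
}

# noiseless model spectrum for a latent parameter vector
model_log_psd <- function(freqs, params, preset) {
  aperiodic_curve(freqs, params[["offset"]], params[["exponent"]]) +
    gaussian_curve(freqs, params[["iaf"]], params[["alpha_level"]],
                   params[["alpha_width"]]) +
    gaussian_curve(freqs, preset$theta_center, params[["theta_level"]],
                   preset$theta_width)
}

#' Forward-simulate a power spectrum from latent parameters
#'
#' Evaluates the generative model on the preset's frequency grid:
#' `log10 power(F) = offset - exponent * log10(F) + alpha Gaussian + theta
#' Gaussian + noise(0, noise_sd)`. With `noise_sd = 0` the output is the exact
#' model curve.
#'
#' @param params Named numeric vector of the six latent parameters
#'   (see [latent-parameters]), e.g. one row of [cohort_latents()].
#' @param preset A [generative_preset].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param noise_sd Override for the preset's bin-noise sd.
#' @return A [power_spectrum] on the log10 scale.
#' @export
generate_spectrum <- function(params, preset, seed = NULL,
                              noise_sd = preset$noise_sd) {
  if (!all(is.finite(params[latent_names]))) {
    stop("latent parameters must be finite", call. = FALSE)
  }
  w <- params[["alpha_width"]]
  if (w <= 0.5 || w >= 12) {
    stop("alpha_width must lie within (0.5, 12) Hz", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  freqs <- preset_freq_grid(preset)
  pw <- model_log_psd(freqs, params, preset)
  if (noise_sd > 0) pw <- pw + rnorm(length(freqs), 0, noise_sd)
  power_spectrum(freqs, pw, "log")
}

#' Synthesize an epoched time series with a target spectrum
#'
#' Random-phase inverse-spectrum synthesis: each 2 s epoch is generated
#' independently on its own discrete frequency grid with amplitudes taken from
#' the target model power spectral density (the generative model extended from
#' 0.5 Hz to Nyquist) and uniformly random phases, so the Welch log-PSD of the
#' signal converges to the model curve as the number of epochs grows. Epoch
#' artifacts (square excursions beyond +/-90 uV) are injected with probability
#' `artifact_rate`.
#'
#' @param params Named latent parameter vector (see [latent-parameters]).
#' @param preset A [generative_preset].
#' @param duration Total duration in seconds (>= 4).
#' @param fs Sampling rate in Hz (>= 100).
#' @param seed Optional integer seed.
#' @param artifact_rate Override for the preset's epoch artifact probability.
#' @return An [epoched_signal] (single channel, 2 s epochs, in uV).
#' @export
generate_timeseries <- function(params, preset, duration = 190, fs = 500,
                                seed = NULL,
                                artifact_rate = preset$artifact_rate) {
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  if (duration < 4) stop("`duration` must be >= 4 s", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  epoch_length <- 2
  n <- as.integer(fs * epoch_length)
  n_epochs <- floor(duration / epoch_length)
  df <- 1 / epoch_length
  k <- seq_len(n %/% 2 - 1L)
  fk <- k * df
  pw_lin <- numeric(length(fk))
  use <- fk >= 0.5
  pw_lin[use] <- 10^model_log_psd(fk[use], params, preset)
  amp <- sqrt(2 * pw_lin * df)

  samples <- matrix(0, n_epochs, n)
  for (e in seq_len(n_epochs)) {
    phi <- runif(length(k), 0, 2 * pi)
    X <- complex(length.out = n)
    X[k + 1L] <- (n / 2) * amp * exp(1i * phi)
    X[n - k + 1L] <- Conj(X[k + 1L])
    samples[e, ] <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  if (artifact_rate > 0) {
    hit <- runif(n_epochs) < artifact_rate
    for (e in which(hit)) {
      at <- sample.int(n - 12L, 1L)
      samples[e, at:(at + 11L)] <- samples[e, at:(at + 11L)] +
        sample(c(-150, 150), 1L)
    }
  }
  epoched_signal(samples, fs = fs, epoch_length = epoch_length)
}
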