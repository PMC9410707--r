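# Shared fixtures: all synthetic, built in code.

default_grid <- function(preset = generative_preset()) preset_freq_grid(preset)

# spectrum that is exactly aperiodic + optional Gaussian peaks (noiseless)
make_spectrum <- function(offset = 1, exponent = 1.5, peaks = NULL,
                          freqs = seq(2, 40, by = 0.25)) {
  pw <- aperiodic_curve(freqs, offset, exponent)
  if (!is.null(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      pw <- pw + gaussian_curve(freqs, peaks[i, 1], peaks[i, 2], peaks[i, 3])
    }
  }
  power_spectrum(freqs, pw, "log")
}

# latent parameter vector in the generator's naming
make_params <- function(offset = 0.8, exponent = 1.5, iaf = 9.5,
                        alpha_level = 0.6, alpha_width = 1.2,
                        theta_level = 0.3) {
  c(offset = offset, exponent = exponent, iaf = iaf, alpha_level = alpha_level,
    alpha_width = alpha_width, theta_level = theta_level)
}

# random latent draws within comfortable generator ranges
random_params <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    offset = runif(n, 0.2, 1.4),
    exponent = runif(n, 0.8, 2.2),
    iaf = runif(n, 8, 12),
    alpha_level = runif(n, 0.3, 0.9),
    alpha_width = runif(n, 0.8, 2.0),
    theta_level = runif(n, 0, 0.4)
  )
}
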