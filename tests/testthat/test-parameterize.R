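test_that("robust aperiodic fit recovers pure 1/f spectra exactly", {
  sp <- make_spectrum(1, 1.5)
  ap <- fit_aperiodic_robust(sp)
  expect_equal(unname(ap), c(1, 1.5), tolerance = 1e-9)

  # flat spectrum: zero slope, intercept at the constant level
  flat <- power_spectrum(seq(2, 40, 0.25), rep(0.7, 153), "log")
  apf <- fit_aperiodic_robust(flat)
  expect_equal(unname(apf), c(0.7, 0), tolerance = 1e-9)
})

test_that("the percentile mask protects the background fit from peaks", {
  sp <- make_spectrum(1, 1.5, peaks = cbind(10, 0.8, 1.5))
  robust <- fit_aperiodic_robust(sp)
  naive <- alphadec:::ap_fit_simple(sp$freqs, sp$power)
  expect_lt(abs(robust[2] - 1.5), 0.05)
  # the single-pass fit must show visibly larger bias than the robust one
  expect_gt(abs(naive[2] - 1.5), 2 * abs(robust[2] - 1.5))
})

test_that("peak extraction finds exact Gaussians and orders by height", {
  freqs <- seq(2, 40, 0.25)
  flat1 <- power_spectrum(freqs, gaussian_curve(freqs, 10, 0.8, 1.5), "log")
  pk <- extract_peaks(flat1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$center, 10, tolerance = 1e-2)
  expect_equal(pk$height, 0.8, tolerance = 1e-2)
  expect_equal(pk$width, 1.5, tolerance = 1e-2)

  flat2 <- power_spectrum(freqs, gaussian_curve(freqs, 6, 0.5, 1) +
                                   gaussian_curve(freqs, 10, 0.8, 1.2), "log")
  pk2 <- extract_peaks(flat2)
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$center[1], 10, tolerance = 0.25)  # taller first
  expect_equal(pk2$center[2], 6, tolerance = 0.25)
})

test_that("raising the minimum peak height extracts fewer peaks", {
  freqs <- seq(2, 40, 0.25)
  set.seed(8)
  counts <- sapply(1:40, function(i) {
    flat <- power_spectrum(freqs, rnorm(153, 0, 0.05), "log")
    c(n0 = nrow(extract_peaks(flat, spectral_settings(min_peak_height = 0))),
      n1 = nrow(extract_peaks(flat, spectral_settings(min_peak_height = 0.1))))
  })
  expect_lt(mean(counts["n1", ]), mean(counts["n0", ]))
})

test_that("full decomposition round-trips a known synthetic spectrum", {
  sp <- make_spectrum(1, 1.2, peaks = cbind(10, 0.7, 1.5))
  fit <- parameterize_spectrum(sp)
  expect_equal(unname(fit$aperiodic[1]), 1, tolerance = 0.05)
  expect_equal(unname(fit$aperiodic[2]), 1.2, tolerance = 0.05)
  expect_equal(fit$peaks$center[1], 10, tolerance = 0.25)
  expect_equal(fit$peaks$height[1], 0.7, tolerance = 0.05)
  expect_equal(fit$peaks$width[1], 1.5, tolerance = 0.3)
  expect_gt(fit$r_squared, 0.999)

  # deterministic: identical fits for identical input
  expect_identical(fit$aperiodic, parameterize_spectrum(sp)$aperiodic)
  expect_identical(fit$peaks, parameterize_spectrum(sp)$peaks)
})

test_that("model spectrum reconstructs and the quality gate flags bad fits", {
  sp <- make_spectrum(1, 1.2, peaks = cbind(10, 0.7, 1.5))
  fit <- parameterize_spectrum(sp)
  # model = aperiodic + sum of Gaussians, exactly
  recon <- aperiodic_curve(fit$freqs, fit$aperiodic[1], fit$aperiodic[2])
  for (i in seq_len(nrow(fit$peaks))) {
    recon <- recon + gaussian_curve(fit$freqs, fit$peaks$center[i],
                                    fit$peaks$height[i], fit$peaks$width[i])
  }
  expect_lt(max(abs(recon - fit$model_spectrum)), 1e-9)
  expect_true(fit$good_fit)

  # heavy noise destroys the fit quality
  set.seed(12)
  noisy <- power_spectrum(sp$freqs, rnorm(153, 0, 1), "log")
  expect_false(parameterize_spectrum(noisy)$good_fit)
})

test_that("periodic spectrum is data minus aperiodic, exactly", {
  sp <- make_spectrum(0.9, 1.4, peaks = cbind(9.5, 0.6, 1.2))
  fit <- parameterize_spectrum(sp)
  per <- periodic_spectrum(sp, fit)
  ap <- aperiodic_curve(sp$freqs, fit$aperiodic[1], fit$aperiodic[2])
  expect_equal(per$power, sp$power - ap, tolerance = 1e-12)

  # pure aperiodic input -> periodic spectrum ~ 0 everywhere
  sp0 <- make_spectrum(0.9, 1.4)
  per0 <- periodic_spectrum(sp0, parameterize_spectrum(sp0))
  expect_lt(max(abs(per0$power)), 1e-6)

  bad <- make_spectrum(0.9, 1.4, freqs = seq(2, 30, 0.25))
  expect_error(periodic_spectrum(bad, fit), "grid")
})

test_that("independent joint-NLS oracle agrees on random noiseless spectra", {
  skip_if_not_installed("minpack.lm")
  pre <- generative_preset()
  draws <- random_params(50, seed = 31)
  for (i in seq_len(nrow(draws))) {
    p <- make_params(draws$offset[i], draws$exponent[i], draws$iaf[i],
                     draws$alpha_level[i], draws$alpha_width[i],
                     draws$theta_level[i])
    sp <- generate_spectrum(p, pre, noise_sd = 0)
    fit <- parameterize_spectrum(sp)
    # one-shot joint nonlinear least squares of the full model, started
    # from neutral values: an independent route to the same decomposition
    df <- data.frame(f = sp$freqs, y = sp$power)
    tc <- pre$theta_center; tw <- pre$theta_width
    nls_fit <- minpack.lm::nlsLM(
      y ~ b - chi * log10(f) + h1 * exp(-(f - c1)^2 / (2 * w1^2)) +
        h2 * exp(-(f - tc)^2 / (2 * tw^2)),
      data = df,
      start = list(b = 1, chi = 1, h1 = 0.3, c1 = 10, w1 = 1, h2 = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- coef(nls_fit)
    expect_lt(abs(fit$aperiodic[1] - cf["b"]), 0.05)
    expect_lt(abs(fit$aperiodic[2] - cf["chi"]), 0.05)
    alpha_pk <- fit$peaks[which.min(abs(fit$peaks$center - cf["c1"])), ]
    expect_lt(abs(alpha_pk$center - cf["c1"]), 0.25)
  }
})

test_that("recovery error grows with measurement noise", {
  pre <- generative_preset()
  p <- make_params()
  err_at <- function(ns) {
    errs <- sapply(1:30, function(s) {
      sp <- generate_spectrum(p, pre, seed = s, noise_sd = ns)
      fit <- parameterize_spectrum(sp)
      abs(fit$aperiodic[2] - p["exponent"])
    })
    mean(errs)
  }
  errs <- sapply(c(0, 0.02, 0.05, 0.1), err_at)
  expect_true(all(diff(errs) >= -1e-6))
})

test_that("noisy synthetic spectra still fit with high explained variance", {
  pre <- generative_preset()
  draws <- random_params(200, seed = 77)
  set.seed(78)
  r2 <- sapply(seq_len(nrow(draws)), function(i) {
    p <- make_params(draws$offset[i], draws$exponent[i], draws$iaf[i],
                     draws$alpha_level[i], draws$alpha_width[i],
                     draws$theta_level[i])
    parameterize_spectrum(generate_spectrum(p, pre, noise_sd = 0.05))$r_squared
  })
  expect_gt(median(r2), 0.97)
})
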