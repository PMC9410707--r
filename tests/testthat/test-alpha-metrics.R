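test_that("IAF detection: argmax in window, border maxima rejected", {
  freqs <- seq(2, 40, 0.25)
  # Gaussian peak at 10 Hz on a flat background
  sp <- power_spectrum(freqs, gaussian_curve(freqs, 10, 0.6, 1.2), "log")
  expect_equal(detect_iaf(sp), 10)

  # monotonically decreasing spectrum: argmax at the 7 Hz border -> absent
  expect_true(is.na(detect_iaf(make_spectrum(1, 1.5))))

  # two peaks, the 8 Hz one taller
  sp2 <- power_spectrum(freqs, gaussian_curve(freqs, 8, 0.8, 1) +
                                 gaussian_curve(freqs, 12, 0.5, 1), "log")
  expect_equal(detect_iaf(sp2), 8)

  short <- power_spectrum(seq(2, 12, 0.25), rep(0, 41), "log")
  expect_error(detect_iaf(short), "search window")
})

test_that("band averaging is inclusive, exact, and Jensen-consistent", {
  freqs <- seq(2, 40, 0.25)
  sp <- power_spectrum(freqs, rep(0.7, length(freqs)), "log")
  expect_equal(band_average(sp, c(8, 13), "log"), 0.7)
  # 8-13 Hz at 0.25 Hz resolution covers exactly 21 bins
  expect_length(alphadec:::band_index(freqs, c(8, 13)), 21L)

  peaked <- make_spectrum(1, 1.5, peaks = cbind(10, 0.8, 1.5))
  lin <- band_average(peaked, c(8, 13), "linear")
  lg <- band_average(peaked, c(8, 13), "log")
  expect_gte(lin, 10^lg)
  expect_error(band_average(sp, c(50, 60)), "band")
})

test_that("compute_metrics fills the parameter set and tracks the IAF band", {
  pre <- generative_preset()
  p <- make_params(alpha_level = 0.8, theta_level = 0)
  sp <- generate_spectrum(p, pre, noise_sd = 0)
  fit <- parameterize_spectrum(sp)
  m <- compute_metrics(sp, fit)
  expect_equal(m$iaf, 9.5, tolerance = 0.3)
  # individualized band for a 10 Hz peak is [6, 12]
  sp10 <- generate_spectrum(make_params(iaf = 10, alpha_level = 0.8,
                                        theta_level = 0), pre, noise_sd = 0)
  m10 <- compute_metrics(sp10, parameterize_spectrum(sp10))
  expect_equal(m10$iaf, 10, tolerance = 0.26)
  band <- c(m10$iaf - 4, m10$iaf + 2)
  expect_equal(m10$total_individualized,
               band_average(sp10, band, "log"), tolerance = 1e-12)
  expect_true(m10$relative_canonical > 0 && m10$relative_individualized > 0)

  # no detectable IAF: individualized fields absent, the rest still produced
  flatish <- make_spectrum(1, 1.5)
  mf <- compute_metrics(flatish, parameterize_spectrum(flatish))
  expect_true(is.na(mf$iaf) && is.na(mf$total_individualized) &&
                is.na(mf$adjusted_individualized))
  expect_false(is.na(mf$total_canonical) || is.na(mf$aperiodic_exponent))
})

test_that("a pure aperiodic offset shift moves total but not adjusted alpha", {
  pre <- generative_preset()
  p1 <- make_params(offset = 0.8, theta_level = 0)
  p2 <- make_params(offset = 1.3, theta_level = 0)
  m1 <- { sp <- generate_spectrum(p1, pre, noise_sd = 0)
          compute_metrics(sp, parameterize_spectrum(sp)) }
  m2 <- { sp <- generate_spectrum(p2, pre, noise_sd = 0)
          compute_metrics(sp, parameterize_spectrum(sp)) }
  expect_equal(m2$total_individualized - m1$total_individualized, 0.5,
               tolerance = 0.02)
  expect_lt(abs(m2$adjusted_individualized - m1$adjusted_individualized), 0.02)
})

test_that("adjusted alpha is zero when the spectrum has no peaks", {
  sp <- make_spectrum(1, 1.5)
  m <- compute_metrics(sp, parameterize_spectrum(sp))
  expect_equal(m$adjusted_canonical, 0, tolerance = 1e-6)
})

test_that("cluster aggregation applies the fit-quality fallback", {
  base <- data.frame(iaf = 10, total_canonical = 1, total_individualized = 1,
                     relative_canonical = 2, relative_individualized = 2,
                     adjusted_canonical = 0.3, adjusted_individualized = 0.3,
                     aperiodic_intercept = 0.8, aperiodic_exponent = 1.5,
                     r_squared = 0.99)
  five <- base[rep(1, 5), ]
  five$total_individualized <- 1:5
  agg <- aggregate_cluster(five)
  expect_equal(agg$total_individualized, 3)
  expect_equal(agg$n_electrodes_used, 5L)

  # one electrode below the gate is dropped
  five$r_squared[2] <- 0.85
  agg2 <- aggregate_cluster(five)
  expect_equal(agg2$n_electrodes_used, 4L)
  expect_equal(agg2$total_individualized, mean(c(1, 3, 4, 5)))

  # identical metrics: aggregation is idempotent
  agg3 <- aggregate_cluster(base[rep(1, 3), ])
  expect_equal(agg3$iaf, base$iaf)
  expect_equal(agg3$aperiodic_exponent, base$aperiodic_exponent)

  # all electrodes poor: flagged, averaged anyway, never excluded on fit alone
  allbad <- five; allbad$r_squared <- 0.5
  agg4 <- aggregate_cluster(allbad)
  expect_true(agg4$all_poor_fit)
  expect_false(agg4$excluded)
  expect_equal(agg4$n_electrodes_used, 5L)

  expect_error(aggregate_cluster(base[0, ]), "at least one")
})

test_that("subjects with no detectable IAF are excluded with a reason", {
  base <- data.frame(iaf = NA_real_, total_canonical = 1,
                     total_individualized = NA_real_, relative_canonical = 2,
                     relative_individualized = NA_real_,
                     adjusted_canonical = 0.3,
                     adjusted_individualized = NA_real_,
                     aperiodic_intercept = 0.8, aperiodic_exponent = 1.5,
                     r_squared = 0.99)
  agg <- aggregate_cluster(base[rep(1, 5), ])
  expect_true(agg$excluded)
  expect_equal(agg$reason, "no_iaf")
})

test_that("outlier flagging is single-pass at mean +/- 3 sd", {
  set.seed(3)
  m <- data.frame(iaf = rep(10, 20), aperiodic_exponent = rnorm(20, 1.5, 0.1))
  m$aperiodic_exponent[20] <- 1.5 + 5 * 0.1 * 10   # far outlier
  m$aperiodic_intercept <- rnorm(20, 0.8, 0.2)
  expect_warning(mask <- flag_outliers(m), "zero variance")  # iaf is constant
  expect_true(mask[20])
  expect_equal(sum(mask), 1L)

  # all-identical values: nothing flagged
  m2 <- data.frame(aperiodic_exponent = rnorm(10))
  expect_false(any(flag_outliers(m2, columns = "aperiodic_exponent") &
                     FALSE))
  expect_error(flag_outliers(m[1:2, ]), "at least 3")
})

test_that("outlier rate under normality matches the compounded 3-sd rate", {
  set.seed(99)
  n <- 4000
  m <- as.data.frame(matrix(rnorm(n * 9), n, 9))
  names(m) <- alphadec:::metric_names
  frac <- mean(flag_outliers(m))
  expected <- 1 - (1 - 2 * pnorm(-3))^9   # ~0.024 for 9 independent params
  expect_equal(frac, expected, tolerance = 0.35)
})
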