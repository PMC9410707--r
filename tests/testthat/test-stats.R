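test_that("gelman_scale gives mean 0 and sd exactly 0.5", {
  expect_equal(gelman_scale(c(1, 2, 3)), c(-0.5, 0, 0.5))
  # two points: halved z-scores under the sample sd
  expect_equal(gelman_scale(c(10, 20)), c(-1, 1) * 5 / (2 * sd(c(10, 20))))
  set.seed(1)
  x <- rexp(100)
  expect_equal(mean(gelman_scale(x)), 0, tolerance = 1e-12)
  expect_equal(sd(gelman_scale(x)), 0.5, tolerance = 1e-12)
  expect_error(gelman_scale(rep(2, 5)), "zero-variance")
})

test_that("effective_tests matches closed-form eigenstructures", {
  expect_equal(effective_tests(diag(5)), 5, tolerance = 1e-9)
  all1 <- matrix(1, 2, 2)
  expect_equal(effective_tests(all1), 1, tolerance = 1e-9)
  eq <- matrix(0.5, 3, 3); diag(eq) <- 1   # eigenvalues {2, 0.5, 0.5}
  expect_equal(effective_tests(eq), 2.5, tolerance = 1e-9)
  expect_error(effective_tests(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("alpha adjustment reproduces the printed significance levels", {
  expect_equal(adjust_alpha(0.05, 1, "sidak")$level, 0.05, tolerance = 1e-12)
  expect_equal(adjust_alpha(0.05, 6, "sidak")$level, 0.008512445,
               tolerance = 1e-6)
  bonf <- adjust_alpha(0.05, 6, "bonferroni")
  expect_equal(bonf$level, 0.05 / 6, tolerance = 1e-12)
  expect_equal(round(bonf$level, 4), 0.0083)            # printed level
  expect_equal(round(bonf$interval_level, 4), 0.9917)   # printed CI coverage
  expect_error(adjust_alpha(1.2, 3), "alpha")
})

test_that("sidak is monotone in Meff and never tighter than bonferroni", {
  meffs <- seq(1, 9, by = 0.5)
  sid <- sapply(meffs, function(m) adjust_alpha(0.05, m, "sidak")$level)
  bon <- sapply(meffs, function(m) adjust_alpha(0.05, m, "bonferroni")$level)
  expect_true(all(diff(sid) < 0))
  expect_true(all(sid >= bon))
})

test_that("OLS backend equals the normal-equations oracle", {
  d <- data.frame(y = c(2.1, 3.9, 6.2, 7.8, 10.1),
                  x1 = c(1, 2, 3, 4, 5), x2 = c(0, 1, 0, 1, 0))
  fit <- fit_outcome_model("y", c("x1", "x2"), d)
  X <- cbind(1, d$x1, d$x2)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$y)   # brute-force normal equations
  expect_equal(fit$estimate, as.numeric(beta_hat), tolerance = 1e-10)

  # noiseless linear outcome is recovered exactly (R warns that the interval
  # of an essentially perfect fit is unreliable; the estimate is what matters)
  d2 <- data.frame(age = rnorm(50))
  d2$y <- 0.4 * d2$age
  f2 <- suppressWarnings(fit_outcome_model("y", "age", d2))
  expect_equal(f2$estimate[f2$term == "age"], 0.4, tolerance = 1e-10)
})

test_that("with both sides gelman-scaled the slope equals the correlation", {
  set.seed(5)
  x <- rnorm(300); y <- 0.6 * x + rnorm(300)
  d <- data.frame(x = gelman_scale(x), y = gelman_scale(y))
  f <- fit_outcome_model("y", "x", d)
  expect_equal(f$estimate[f$term == "x"], cor(x, y), tolerance = 1e-10)
})

test_that("rank deficiency is reported with the collinear column named", {
  set.seed(6)
  d <- data.frame(y = rnorm(20), fa_left = rnorm(20))
  d$fa_right <- d$fa_left
  expect_error(fit_outcome_model("y", c("fa_left", "fa_right"), d),
               "fa_right")
  expect_error(fit_outcome_model("y", c("x", "z"), d), "not present")
})

test_that("significance flag follows interval-excludes-zero", {
  set.seed(7)
  d <- data.frame(x = rnorm(200))
  d$y <- 0.5 * d$x + rnorm(200, 0, 0.5)
  d$z <- rnorm(200)
  f <- fit_outcome_model("y", c("x", "z"), d, interval_level = 0.9917)
  expect_true(f$significant[f$term == "x"])
  expect_false(f$significant[f$term == "z"])
  expect_true(all(f$lower <= f$estimate & f$estimate <= f$upper))
})

test_that("correlation_table uses complete cases and is symmetric", {
  d <- data.frame(a = c(1:9, NA), b = c(2 * (1:9), 5))
  ct <- correlation_table(d)
  expect_equal(ct["a", "b"], 1, tolerance = 1e-12)
  expect_equal(diag(ct), c(a = 1, b = 1))
  set.seed(8)
  big <- as.data.frame(matrix(rnorm(10000 * 2), ncol = 2))
  expect_lt(abs(correlation_table(big)[1, 2]), 0.05)
  expect_error(correlation_table(d[1:2, ]), "at least 3")
})

test_that("bayes backend with wide priors agrees with OLS", {
  skip_if_not_installed("rjags")
  set.seed(9)
  d <- data.frame(x = rnorm(200))
  d$y <- 0.5 * d$x + rnorm(200, 0, 0.5)
  ols <- fit_outcome_model("y", "x", d)
  bay <- fit_outcome_model("y", "x", d, backend = "bayes",
                           n_iter = 3000, n_burnin = 500, seed = 4)
  expect_equal(bay$estimate[bay$term == "x"], ols$estimate[ols$term == "x"],
               tolerance = 0.05)
  expect_false(is.null(attr(bay, "draws")))
})

test_that("posterior extraction and sequential updating shrink as expected", {
  skip_if_not_installed("rjags")
  set.seed(10)
  stage1 <- data.frame(x = rnorm(400))
  stage1$y <- 0.3 * stage1$x + rnorm(400, 0, 0.3)
  m1 <- fit_outcome_model("y", "x", stage1, backend = "bayes",
                          n_iter = 3000, n_burnin = 500, seed = 1)
  pri <- posterior_to_prior(m1)
  expect_named(pri, c("(Intercept)", "x"))
  expect_equal(unname(pri$x["location"]), 0.3, tolerance = 0.05)

  # tiny stage-2 data with a very different raw slope: the informative prior
  # pulls the posterior toward the stage-1 estimate
  set.seed(11)
  stage2 <- data.frame(x = rnorm(8))
  stage2$y <- 1.5 * stage2$x + rnorm(8, 0, 1)
  flat <- fit_outcome_model("y", "x", stage2, backend = "bayes",
                            n_iter = 3000, n_burnin = 500, seed = 2)
  informed <- fit_outcome_model("y", "x", stage2, backend = "bayes",
                                priors = pri, n_iter = 3000, n_burnin = 500,
                                seed = 2)
  b_flat <- flat$estimate[flat$term == "x"]
  b_inf <- informed$estimate[informed$term == "x"]
  expect_lt(abs(b_inf - 0.3), abs(b_flat - 0.3))

  # near-flat stage-1 posterior: stage-2 fit is essentially stand-alone
  wide <- list(x = c(location = 0, scale = 50),
               `(Intercept)` = c(location = 0, scale = 50))
  loose <- fit_outcome_model("y", "x", stage2, backend = "bayes",
                             priors = wide, n_iter = 3000, n_burnin = 500,
                             seed = 2)
  expect_equal(loose$estimate[loose$term == "x"], b_flat, tolerance = 0.15)

  ols <- fit_outcome_model("y", "x", stage2)
  expect_error(posterior_to_prior(ols), "draws")
})
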