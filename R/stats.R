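#' Gelman 0.5-sd scaling
#'
#' Scales a numeric variable to mean 0 and standard deviation 0.5 by
#' `(x - mean(x)) / (2 * sd(x))`, so that coefficients of continuous predictors
#' are comparable to those of untransformed binary predictors.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return The scaled vector.
#' @export
gelman_scale <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot scale a zero-variance variable", call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / (2 * s)
}

#' Effective number of tests
#'
#' Eigenvalue-based estimate of the number of independent comparisons among M
#' correlated outcomes: `Meff = 1 + (M - 1) * (1 - Var(lambda) / M)` with
#' `lambda` the eigenvalues of the outcome correlation matrix and `Var` the
#' sample variance (denominator `M - 1`).
#'
#' @param corr_matrix Correlation matrix of the M outcomes.
#' @return `Meff`, a value in `[1, M]`.
#' @export
effective_tests <- function(corr_matrix) {
  if (!is.matrix(corr_matrix) ||
      nrow(corr_matrix) != ncol(corr_matrix) ||
      max(abs(corr_matrix - t(corr_matrix))) > 1e-8) {
    stop("`corr_matrix` must be a symmetric square matrix", call. = FALSE)
  }
  M <- nrow(corr_matrix)
  lambda <- eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values
  1 + (M - 1) * (1 - stats::var(lambda) / M)
}

#' Multiplicity-adjusted significance level
#'
#' Adjusts a nominal level for `Meff` effective tests. `sidak` gives
#' `1 - (1 - alpha)^(1/Meff)`; `bonferroni` gives `alpha / Meff`. The
#' complementary `interval_level = 1 - adjusted` is the credible/confidence
#' level at which interval-excludes-zero matches the adjusted test.
#'
#' @param alpha Nominal level in (0, 1) (default 0.05).
#' @param meff Effective number of tests (>= 1), see [effective_tests()].
#' @param method `"sidak"` or `"bonferroni"`.
#' @return List with `level` (adjusted significance level) and
#'   `interval_level`.
#' @export
adjust_alpha <- function(alpha = 0.05, meff, method = c("sidak", "bonferroni")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (meff < 1) stop("`meff` must be >= 1", call. = FALSE)
  level <- switch(method,
                  sidak = 1 - (1 - alpha)^(1 / meff),
                  bonferroni = alpha / meff)
  list(level = level, interval_level = 1 - level)
}

#' Fit an outcome regression model
#'
#' Fits `outcome ~ predictors` on a data table whose numeric variables are
#' expected to be already standardized (e.g. [gelman_scale()]d). The `ols`
#' backend gives least-squares estimates with analytic intervals at
#' `interval_level`; the `bayes` backend samples the posterior under the
#' configured priors (default uninformative Cauchy, location 0, scale 2.5) via
#' JAGS and reports posterior means with equal-tailed credible intervals.
#' Both flag a predictor significant when its interval excludes zero.
#' Categorical predictors are treatment-coded with the first level as
#' reference.
#'
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @param data Data frame.
#' @param backend `"ols"` (default) or `"bayes"`.
#' @param interval_level Interval coverage in (0.5, 1) (default 0.95).
#' @param priors For the bayes backend: either `NULL` (Cauchy(0, 2.5) on all
#'   coefficients) or a named list of `c(location, scale)` normal priors per
#'   coefficient (as produced by [posterior_to_prior()]); coefficients without
#'   an entry keep the Cauchy prior.
#' @param n_iter,n_burnin MCMC length for the bayes backend.
#' @param seed Seed for the bayes backend sampler.
#' @return A `model_result`: data frame with `term`, `estimate`, `lower`,
#'   `upper`, `significant`; posterior draws (bayes) are attached as an
#'   attribute for [posterior_to_prior()].
#' @export
fit_outcome_model <- function(outcome, predictors, data,
                              backend = c("ols", "bayes"),
                              interval_level = 0.95, priors = NULL,
                              n_iter = 4000L, n_burnin = 1000L, seed = 1L) {
  backend <- match.arg(backend)
  if (interval_level <= 0.5 || interval_level >= 1) {
    stop("`interval_level` must be in (0.5, 1)", call. = FALSE)
  }
  missing_vars <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_vars)) {
    stop("variables not present in data: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  form <- stats::reformulate(predictors, response = outcome)
  mf <- stats::model.frame(form, data = data)
  X <- stats::model.matrix(form, mf)
  y <- stats::model.response(mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (backend == "ols") {
    fit <- stats::lm(form, data = data)
    est <- stats::coef(fit)
    ci <- stats::confint(fit, level = interval_level)
    res <- data.frame(term = names(est), estimate = unname(est),
                      lower = ci[, 1], upper = ci[, 2], row.names = NULL)
    draws <- NULL
  } else {
    res_draws <- jags_lm(y, X, priors, interval_level, n_iter, n_burnin, seed)
    res <- res_draws$summary
    draws <- res_draws$draws
  }
  res$significant <- res$lower > 0 | res$upper < 0
  structure(res, class = c("model_result", "data.frame"),
            backend = backend, interval_level = interval_level, draws = draws,
            outcome = outcome)
}

# Bayesian linear model via JAGS: Cauchy(0, 2.5) priors (t with 1 df) unless a
# normal prior is supplied per coefficient
jags_lm <- function(y, X, priors, interval_level, n_iter, n_burnin, seed) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("the bayes backend requires the rjags package", call. = FALSE)
  }
  p <- ncol(X)
  prior_type <- integer(p)          # 0 = cauchy, 1 = normal
  prior_loc <- numeric(p)
  prior_prec <- rep(1 / 2.5^2, p)
  if (!is.null(priors)) {
    for (j in seq_len(p)) {
      pj <- priors[[colnames(X)[j]]]
      if (!is.null(pj)) {
        prior_type[j] <- 1L
        prior_loc[j] <- pj[1]
        prior_prec[j] <- 1 / pj[2]^2
      }
    }
  }
  model_string <- "
    model {
      for (i in 1:n) { y[i] ~ dnorm(inprod(X[i,], beta), tau) }
      for (j in 1:p) {
        beta_c[j] ~ dt(0, 0.16, 1)
        beta_n[j] ~ dnorm(loc[j], prec[j])
        beta[j] <- ifelse(type[j] == 1, beta_n[j], beta_c[j])
      }
      tau ~ dgamma(0.001, 0.001)
    }"
  jm <- rjags::jags.model(
    textConnection(model_string),
    data = list(y = as.numeric(y), X = X, n = length(y), p = p,
                type = prior_type, loc = prior_loc, prec = prior_prec),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seed),
    n.chains = 1L, quiet = TRUE
  )
  update(jm, n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "beta", n.iter = n_iter,
                              progress.bar = "none")[[1]]
  draws <- as.matrix(samp)
  colnames(draws) <- colnames(X)
  a <- (1 - interval_level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a))
  list(summary = data.frame(term = colnames(X),
                            estimate = colMeans(draws),
                            lower = qs[1, ], upper = qs[2, ],
                            row.names = NULL),
       draws = draws)
}

#' Pairwise Pearson correlations of a metric table
#'
#' Complete cases only (listwise deletion).
#'
#' @param metrics Data frame; numeric columns are used.
#' @param columns Optional subset of columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_table <- function(metrics, columns = NULL) {
  num <- metrics[vapply(metrics, is.numeric, logical(1))]
  if (!is.null(columns)) num <- num[columns]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  if (nrow(num) < 3L) stop("need at least 3 complete cases", call. = FALSE)
  stats::cor(as.matrix(num))
}

#' Approximate a posterior as priors for a subsequent fit
#'
#' Takes the stored posterior draws of a bayes-backend [fit_outcome_model()]
#' result and emits, per coefficient, a parametric approximation to be used as
#' the prior in an independent cohort's fit (sequential updating). The default
#' normal family is moment-matched (mean/sd of the draws).
#'
#' @param result A bayes-backend `model_result`.
#' @param family Approximation family; `"normal"` is implemented.
#' @param terms Coefficients to extract (default: all).
#' @return Named list of `c(location, scale)` per coefficient, suitable for the
#'   `priors` argument of [fit_outcome_model()].
#' @export
posterior_to_prior <- function(result, family = "normal", terms = NULL) {
  draws <- attr(result, "draws")
  if (is.null(draws)) {
    stop("result has no stored posterior draws (use backend = 'bayes')", call. = FALSE)
  }
  if (!identical(family, "normal")) {
    stop("only the normal approximation family is implemented", call. = FALSE)
  }
  if (is.null(terms)) terms <- colnames(draws)
  out <- lapply(terms, function(tm) c(location = mean(draws[, tm]),
                                      scale = stats::sd(draws[, tm])))
  names(out) <- terms
  out
}
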