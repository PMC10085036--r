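#' Elicit gamma prior hyperparameters for the MKTL parameters
#'
#' Builds independent gamma priors for `theta` and `beta` by moment-matching
#' a matrix of estimate replicates: for each parameter the gamma shape is
#' `mean^2 / variance` and the rate is `mean / variance` of the B replicate
#' values, so the prior mean and variance equal the replicate mean and
#' variance exactly.
#'
#' `mktl_elicit_prior()` generates the replicates from a maximum-likelihood
#' fit.  The default (`method = "normal"`) draws them from the asymptotic
#' normal law of the estimator, `N(estimate, vcov)`, i.e. directly from the
#' estimate and variance-covariance matrix of the fit; draws with a
#' non-positive component are discarded.  `method = "bootstrap"` refits the
#' model to B parametric-bootstrap resamples instead, which is slower and
#' inherits any small-sample bias of the estimator.
#'
#' @param fit An `"mktl_mle"` object.
#' @param B Number of replicates (default 1000).
#' @param method `"normal"` (default) or `"bootstrap"`; see Details.
#' @param seed Optional integer seed for the replicate draws.
#' @return An object of class `"mktl_prior"`: a list with fields `phi1`,
#'   `d1` (gamma shape/rate for `theta`), `phi2`, `d2` (for `beta`), plus
#'   `B`, `method` metadata.
#' @examples
#' fit <- mktl_fit_mle(covid_mortality())
#' prior <- mktl_elicit_prior(fit, B = 200, seed = 1)
#' prior
#' @export
mktl_elicit_prior <- function(fit, B = 1000L, method = c("normal", "bootstrap"),
                              seed = NULL) {
  stopifnot(inherits(fit, "mktl_mle"))
  method <- match.arg(method)
  if (B < 2L) abort("`B` must be at least 2.")
  if (!is.null(seed)) set.seed(seed)
  if (method == "normal") {
    S <- chol(fit$vcov)
    reps <- matrix(rnorm(2L * B), B, 2L) %*% S
    reps <- sweep(reps, 2L, c(fit$theta, fit$beta), "+")
    reps <- reps[reps[, 1] > 0 & reps[, 2] > 0, , drop = FALSE]
    if (nrow(reps) < 2L) abort("too few positive replicate draws.")
  } else {
    reps <- t(vapply(seq_len(B), function(b) {
      xb <- rmktl(fit$n_obs, fit$theta, fit$beta)
      fb <- mktl_fit_mle(xb, init = c(fit$theta, fit$beta))
      c(fb$theta, fb$beta)
    }, numeric(2)))
  }
  out <- gamma_moment_match(reps)
  out$B <- nrow(reps)
  out$method <- method
  out
}

#' Moment-match gamma hyperparameters to estimate replicates
#'
#' The raw elicitation rule behind [mktl_elicit_prior()]: given a B x 2
#' matrix whose columns are replicate estimates of `theta` and `beta`,
#' returns `phi = mean^2/var` and `rate = mean/var` per column.
#'
#' @param replicates A B x 2 numeric matrix of positive estimates
#'   (columns: theta, beta), B >= 2.
#' @return An `"mktl_prior"` object.
#' @export
gamma_moment_match <- function(replicates) {
  replicates <- as.matrix(replicates)
  if (ncol(replicates) != 2L || nrow(replicates) < 2L)
    abort("`replicates` must be a B x 2 matrix with B >= 2.")
  m <- colMeans(replicates)
  v <- apply(replicates, 2L, var)
  if (any(v <= 0)) abort("zero-variance replicate column: prior would be degenerate.")
  structure(list(phi1 = unname(m[1]^2 / v[1]), d1 = unname(m[1] / v[1]),
                 phi2 = unname(m[2]^2 / v[2]), d2 = unname(m[2] / v[2])),
            class = "mktl_prior")
}

#' @export
print.mktl_prior <- function(x, ...) {
  cat("Independent gamma priors for the MKTL parameters\n")
  cat(sprintf("  theta ~ Gamma(shape %.4f, rate %.4f)  mean %.4f, sd %.4f\n",
              x$phi1, x$d1, x$phi1 / x$d1, sqrt(x$phi1) / x$d1))
  cat(sprintf("  beta  ~ Gamma(shape %.4f, rate %.4f)  mean %.4f, sd %.4f\n",
              x$phi2, x$d2, x$phi2 / x$d2, sqrt(x$phi2) / x$d2))
  if (!is.null(x$method))
    cat(sprintf("  elicited from %d %s replicates\n", x$B, x$method))
  invisible(x)
}

#' Log posterior density of the MKTL parameters (up to a constant)
#'
#' Log-likelihood plus independent gamma log-prior kernels:
#' \eqn{(\phi_1-1)\log\theta - D_1\theta + (\phi_2-1)\log\beta - D_2\beta}.
#' Returns `-Inf` for non-positive parameters.
#'
#' @param theta,beta Parameter values.
#' @param x Numeric data vector in (0, 1).
#' @param prior An `"mktl_prior"` object.
#' @return A single number.
#' @export
mktl_log_posterior <- function(theta, beta, x, prior) {
  stopifnot(inherits(prior, "mktl_prior"))
  if (!is.finite(theta) || !is.finite(beta) || theta <= 0 || beta <= 0)
    return(-Inf)
  mktl_loglik(x, theta, beta) +
    (prior$phi1 - 1) * log(theta) - prior$d1 * theta +
    (prior$phi2 - 1) * log(beta) - prior$d2 * beta
}

#' Bayesian fit of the MKTL distribution by random-walk Metropolis-Hastings
#'
#' Samples the posterior of \eqn{(\theta,\beta)} under independent gamma
#' priors with a bivariate normal random-walk proposal.  With
#' `proposal_scale = "auto"` the proposal covariance is the MLE covariance
#' scaled by \eqn{2.4^2/2}, the classical random-walk tuning for two
#' dimensions.  Proposals with a non-positive component are rejected, which
#' is equivalent to their zero prior mass.
#'
#' @inheritParams mktl_fit_mle
#' @param prior An `"mktl_prior"` object, or `NULL` to elicit one from the
#'   MLE fit via [mktl_elicit_prior()].
#' @param n_iter Total chain length (default 10000).
#' @param burn_in Discarded initial iterations (default 2000).
#' @param seed Integer seed; the chain is fully reproducible for a fixed
#'   seed.
#' @param proposal_scale `"auto"` or a 2 x 2 covariance matrix for the
#'   random-walk proposal.
#' @param B Replicates used when the prior is elicited internally.
#' @param level Credible level for the HPD intervals (default 0.95).
#'
#' @return An object of class `"mktl_bayes"`: a list with `draws` (tibble
#'   with columns `iteration`, `theta`, `beta`, post burn-in), posterior
#'   means `theta`/`beta`, `sd`, `hpd` (tibble), `acceptance_rate`,
#'   `n_iter`, `burn_in`, `prior`, `mle` and `seed`.  Supports [tidy()],
#'   [glance()], [autoplot()] and `print()`.
#'
#' @examples
#' fit <- mktl_fit_bayes(covid_mortality(), n_iter = 2000, burn_in = 500,
#'                       seed = 1)
#' tidy(fit)
#' @export
mktl_fit_bayes <- function(data, col = NULL, prior = NULL, n_iter = 10000L,
                           burn_in = 2000L, seed = NULL,
                           proposal_scale = "auto", B = 1000L, level = 0.95) {
  x <- extract_sample(data, col)
  validate_sample(x, n_min = 3L)
  if (burn_in < 0L || n_iter <= burn_in)
    abort("`n_iter` must exceed `burn_in` (and burn_in must be >= 0).")
  if (!is.null(seed)) set.seed(seed)

  mle <- mktl_fit_mle(x)
  if (is.null(prior)) prior <- mktl_elicit_prior(mle, B = B)
  stopifnot(inherits(prior, "mktl_prior"))

  P <- if (identical(proposal_scale, "auto")) {
    chol(mle$vcov * 2.4^2 / 2)
  } else {
    stopifnot(is.matrix(proposal_scale), all(dim(proposal_scale) == 2L))
    chol(proposal_scale)
  }

  cur <- c(mle$theta, mle$beta)
  lcur <- mktl_log_posterior(cur[1], cur[2], x, prior)
  chain <- matrix(NA_real_, n_iter, 2L)
  acc <- 0L
  for (i in seq_len(n_iter)) {
    prop <- cur + drop(rnorm(2L) %*% P)
    lprop <- mktl_log_posterior(prop[1], prop[2], x, prior)
    if (is.finite(lprop) && log(runif(1L)) < lprop - lcur) {
      cur <- prop
      lcur <- lprop
      acc <- acc + 1L
    }
    chain[i, ] <- cur
  }
  if (acc == 0L) abort("Metropolis-Hastings chain rejected every proposal.")

  keep <- seq.int(burn_in + 1L, n_iter)
  draws <- tibble(iteration = keep,
                  theta = chain[keep, 1L], beta = chain[keep, 2L])
  hpd <- tibble(
    term = c("theta", "beta"),
    estimate = c(mean(draws$theta), mean(draws$beta)),
    std.error = c(sd(draws$theta), sd(draws$beta)),
    conf.low = c(hpd_interval(draws$theta, level)[1],
                 hpd_interval(draws$beta, level)[1]),
    conf.high = c(hpd_interval(draws$theta, level)[2],
                  hpd_interval(draws$beta, level)[2])
  )
  structure(list(
    draws = draws,
    theta = hpd$estimate[1],
    beta = hpd$estimate[2],
    sd = setNames(hpd$std.error, c("theta", "beta")),
    hpd = hpd,
    acceptance_rate = acc / n_iter,
    n_iter = n_iter,
    burn_in = burn_in,
    prior = prior,
    mle = mle,
    level = level,
    seed = seed,
    data = x
  ), class = "mktl_bayes")
}

#' Posterior mean under squared-error loss
#'
#' The Bayes estimator under squared-error loss is the posterior mean;
#' this returns the component-wise mean of the post-burn-in draws.
#'
#' @param fit An `"mktl_bayes"` object.
#' @return Named numeric vector `c(theta = ..., beta = ...)`.
#' @export
self_estimate <- function(fit) {
  stopifnot(inherits(fit, "mktl_bayes"))
  if (nrow(fit$draws) == 0L) abort("empty chain.")
  c(theta = mean(fit$draws$theta), beta = mean(fit$draws$beta))
}

#' Highest posterior density interval from MCMC draws
#'
#' Chen-Shao sliding-window HPD: the draws are sorted, every window of
#' `ceiling(level * M)` consecutive order statistics is considered, and the
#' narrowest window is returned (leftmost on ties).
#'
#' @param draws Numeric vector of at least 50 posterior draws.
#' @param level Credible level in (0, 1).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rnorm(1000), 0.95)
#' @export
hpd_interval <- function(draws, level = 0.95) {
  if (length(draws) < 50L) abort("at least 50 draws are required.")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    abort("`level` must be a single number strictly inside (0, 1).")
  d <- sort(draws)
  M <- length(d)
  k <- ceiling(level * M)
  widths <- d[k:M] - d[1:(M - k + 1L)]
  j <- which.min(widths)             # which.min takes the leftmost tie
  c(d[j], d[j + k - 1L])
}

#' @export
print.mktl_bayes <- function(x, ...) {
  cat("MKTL Bayesian fit (random-walk Metropolis-Hastings)\n")
  cat(sprintf("  %d iterations, %d burn-in, acceptance rate %.3f\n",
              x$n_iter, x$burn_in, x$acceptance_rate))
  cat(sprintf("  posterior mean theta = %.4f (sd %.4f)\n",
              x$theta, x$sd["theta"]))
  cat(sprintf("  posterior mean beta  = %.4f (sd %.4f)\n",
              x$beta, x$sd["beta"]))
  invisible(x)
}

#' @rdname mktl_fit_bayes
#' @param x,object An `"mktl_bayes"` object.
#' @param ... Unused.
#' @method tidy mktl_bayes
#' @export
tidy.mktl_bayes <- function(x, ...) {
  x$hpd
}

#' @rdname mktl_fit_bayes
#' @method glance mktl_bayes
#' @export
glance.mktl_bayes <- function(x, ...) {
  tibble(
    n_iter = x$n_iter,
    burn_in = x$burn_in,
    n_draws = nrow(x$draws),
    acceptance_rate = x$acceptance_rate,
    nobs = length(x$data)
  )
}

#' @rdname mktl_fit_bayes
#' @method autoplot mktl_bayes
#' @export
autoplot.mktl_bayes <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws, c("theta", "beta"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "#2166ac") +
    ggplot2::facet_wrap(~parameter, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Metropolis-Hastings trace (post burn-in)") +
    ggplot2::theme_minimal()
}
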