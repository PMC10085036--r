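#' Probability integral transform under a fitted MKTL model
#'
#' Sorted values of the fitted CDF at the observations,
#' \eqn{u_{(i)} = F(x_{(i)})}.  If the model is correct these behave like
#' uniform order statistics, which is what the goodness-of-fit statistics
#' measure.  Ties produce a warning (the statistics remain computable).
#'
#' @param x Numeric vector of observations in (0, 1).
#' @param theta,beta Positive shape parameters.
#' @return Sorted numeric vector in (0, 1).
#' @export
pit_transform <- function(x, theta, beta) {
  check_shapes(theta, beta)
  validate_sample(x)
  if (anyDuplicated(x)) warn("tied observations: the PIT values contain ties.")
  sort(pmktl(x, theta, beta))
}

#' Goodness-of-fit statistics for a fitted MKTL model
#'
#' Kolmogorov-Smirnov distance (with its exact small-sample p-value),
#' Cramer-von Mises \eqn{W} and Anderson-Darling \eqn{A}, all computed from
#' the probability integral transform of the data under the fitted
#' parameters:
#' \deqn{D = \max_i \max\{i/n - u_{(i)},\ u_{(i)} - (i-1)/n\},}
#' \deqn{W = \frac{1}{12n} + \sum_i \left(u_{(i)} - \frac{2i-1}{2n}\right)^2,}
#' \deqn{A = -n - \frac{1}{n}\sum_i (2i-1)\left[\ln u_{(i)} +
#'   \ln(1 - u_{(n+1-i)})\right].}
#'
#' The statistics are evaluated at the *fitted* (not hypothesized)
#' parameters, the convention used when ranking candidate models on the
#' same data; the KS p-value is therefore approximate in the usual
#' "fit statistics" sense.
#'
#' @param fit An `"mktl_mle"` object, or a numeric data vector if `theta`
#'   and `beta` are given explicitly.
#' @param theta,beta Optional explicit parameters when `fit` is a data
#'   vector.
#' @return A one-row tibble of class `"mktl_gof"` with columns `ks`,
#'   `ks_pvalue`, `W`, `A`, `n`.
#' @examples
#' mktl_gof(mktl_fit_mle(covid_mortality()))
#' @export
mktl_gof <- function(fit, theta = NULL, beta = NULL) {
  if (inherits(fit, "mktl_mle")) {
    x <- fit$data
    theta <- fit$theta
    beta <- fit$beta
  } else {
    x <- extract_sample(fit)
    if (is.null(theta) || is.null(beta))
      abort("supply `theta` and `beta` when `fit` is a data vector.")
  }
  u <- pit_transform(x, theta, beta)
  n <- length(u)
  out <- tibble(
    ks = ks_statistic(u),
    ks_pvalue = suppressWarnings(ks.test(u, "punif")$p.value),
    W = cvm_statistic(u),
    A = ad_statistic(u),
    n = n
  )
  class(out) <- c("mktl_gof", class(out))
  out
}

#' Individual goodness-of-fit statistics from sorted PIT values
#'
#' Building blocks of [mktl_gof()], operating directly on a sorted vector
#' of probability-integral-transform values.
#'
#' @param u Sorted numeric vector strictly inside (0, 1).
#' @return A single number.
#' @export
ks_statistic <- function(u) {
  u <- check_pit(u)
  n <- length(u)
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

#' @rdname ks_statistic
#' @export
cvm_statistic <- function(u) {
  u <- check_pit(u)
  n <- length(u)
  i <- seq_len(n)
  1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
}

#' @rdname ks_statistic
#' @export
ad_statistic <- function(u) {
  u <- check_pit(u)
  n <- length(u)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log1p(-rev(u))))
}

check_pit <- function(u) {
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    abort("PIT values must lie strictly inside (0, 1).")
  if (is.unsorted(u)) u <- sort(u)
  u
}
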