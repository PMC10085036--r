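#' The modified Kies Topp-Leone (MKTL) distribution
#'
#' Density, distribution function, quantile function, random generation,
#' survival and hazard rate for the two-parameter MKTL distribution with
#' shape parameters `theta` and `beta`, supported on the open unit interval.
#'
#' The MKTL distribution arises by inserting the Topp-Leone CDF
#' \eqn{G(x;\beta) = [x(2-x)]^\beta} into the modified Kies generator, giving
#' \deqn{F(x;\theta,\beta) = 1 - \exp\{-[G/(1-G)]^\theta\}, \qquad 0<x<1.}
#' Both parameters are shapes: `beta` is inherited from the Topp-Leone
#' baseline and `theta` from the modified Kies generator.  Depending on
#' \eqn{(\theta,\beta)} the hazard rate is increasing, decreasing, or
#' bathtub-shaped, which is what makes the family useful for bounded
#' lifetime data such as daily mortality rates.
#'
#' The odds term \eqn{[G/(1-G)]^\theta} is evaluated in log space, and
#' \eqn{\log G} uses `log1p(-(1-x)^2)` near the upper end of the support,
#' so tail evaluations stay finite and monotone in double precision.
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities, strictly inside (0, 1).
#' @param n Number of draws.
#' @param theta Positive shape parameter of the modified Kies generator.
#' @param beta Positive shape parameter of the Topp-Leone baseline.
#' @param log,log.p Logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail Logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#' @param seed Optional integer; if supplied, `rmktl()` seeds the RNG before
#'   drawing so the sample is reproducible.
#'
#' @return `dmktl()` gives the density (0 outside the support), `pmktl()` the
#'   distribution function (clamped to 0/1 outside the support), `qmktl()`
#'   the quantile function, `rmktl()` a vector of draws by inversion
#'   sampling, `smktl()` the survival function and `hmktl()` the hazard
#'   rate. `hmktl()` raises an error for arguments outside the open unit
#'   interval, where the hazard is undefined.
#'
#' @examples
#' pmktl(0.5, theta = 1, beta = 1)      # 1 - exp(-3)
#' qmktl(0.5, theta = 1, beta = 1)
#' x <- rmktl(500, theta = 3, beta = 0.5, seed = 1)
#' hmktl(0.5, theta = 1, beta = 1)      # = dmktl / smktl = 16
#' @name mktl-distribution
NULL

# validates the two shape parameters (scalar, positive, finite)
check_shapes <- function(theta, beta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    abort("`theta` must be a single positive finite number.")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    abort("`beta` must be a single positive finite number.")
  invisible(NULL)
}

# log[x(2-x)] for x in (0,1); the log1p branch avoids cancellation as x -> 1
# where x(2-x) = 1 - (1-x)^2
log_g1 <- function(x) {
  out <- numeric(length(x))
  hi <- x > 0.5
  out[hi] <- log1p(-(1 - x[hi])^2)
  out[!hi] <- log(x[!hi]) + log(2 - x[!hi])
  out
}

# log G, log(1-G) and the log odds log[G/(1-G)] for the TL baseline at shape
# beta; x must be strictly inside (0,1)
mktl_logs <- function(x, theta, beta) {
  lG <- beta * log_g1(x)        # < 0
  l1mG <- log(-expm1(lG))
  list(lG = lG, l1mG = l1mG, lodds = lG - l1mG)
}

#' Topp-Leone distribution function
#'
#' CDF of the one-parameter Topp-Leone baseline,
#' \eqn{G(x;\beta) = [x(2-x)]^\beta} on the open unit interval.  This is the
#' generating CDF of the MKTL family.
#'
#' @param q Vector of quantiles, each strictly inside (0, 1).
#' @param beta Positive shape parameter.
#' @return Vector of probabilities in (0, 1).
#' @examples
#' ptl(0.5, beta = 1)   # 0.75
#' @export
ptl <- function(q, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    abort("`beta` must be a single positive finite number.")
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    abort("`q` must lie strictly inside the unit interval (0, 1).")
  exp(beta * log_g1(q))
}

#' @rdname mktl-distribution
#' @export
dmktl <- function(x, theta, beta, log = FALSE) {
  check_shapes(theta, beta)
  out <- rep(if (log) -Inf else 0, length(x))
  ok <- is.finite(x) & x > 0 & x < 1
  if (any(ok)) {
    xi <- x[ok]
    lg <- mktl_logs(xi, theta, beta)
    ld <- log(2 * beta * theta) + (beta * theta - 1) * log_g1(xi) +
      log1p(-xi) - (theta + 1) * lg$l1mG - exp(theta * lg$lodds)
    out[ok] <- if (log) ld else exp(ld)
  }
  out[is.na(x)] <- NA_real_
  out
}

#' @rdname mktl-distribution
#' @export
pmktl <- function(q, theta, beta, lower.tail = TRUE, log.p = FALSE) {
  check_shapes(theta, beta)
  lsf <- rep(NA_real_, length(q))          # log survival
  lsf[!is.na(q) & q <= 0] <- 0
  lsf[!is.na(q) & q >= 1] <- -Inf
  ok <- !is.na(q) & q > 0 & q < 1
  if (any(ok)) {
    lg <- mktl_logs(q[ok], theta, beta)
    lsf[ok] <- -exp(theta * lg$lodds)
  }
  if (lower.tail) {
    p <- -expm1(lsf)
    if (log.p) log(p) else p
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' @rdname mktl-distribution
#' @export
smktl <- function(q, theta, beta) {
  pmktl(q, theta, beta, lower.tail = FALSE)
}

#' @rdname mktl-distribution
#' @export
hmktl <- function(x, theta, beta) {
  check_shapes(theta, beta)
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    abort("the hazard rate is defined only strictly inside (0, 1).")
  lg <- mktl_logs(x, theta, beta)
  # log f - log S; the exp{-odds^theta} factor cancels
  exp(log(2 * beta * theta) + (beta * theta - 1) * log_g1(x) +
        log1p(-x) - (theta + 1) * lg$l1mG)
}

#' @rdname mktl-distribution
#' @export
qmktl <- function(p, theta, beta) {
  check_shapes(theta, beta)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    abort("`p` must lie strictly inside the unit interval (0, 1).")
  # invert F: odds^theta = -log(1-p); G = w/(1+w); x = 1 - sqrt(1 - G^(1/beta))
  lw <- log(-log1p(-p)) / theta              # log odds
  lG <- lw - log1p(exp(lw))                  # log G = log w - log(1+w)
  1 - sqrt(-expm1(lG / beta))
}

#' @rdname mktl-distribution
#' @export
rmktl <- function(n, theta, beta, seed = NULL) {
  check_shapes(theta, beta)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    abort("`n` must be a positive integer.")
  if (!is.null(seed)) set.seed(seed)
  qmktl(runif(n), theta, beta)
}

#' Raw moments of the MKTL distribution
#'
#' Computes \eqn{E[X^r]} by adaptive quadrature of \eqn{x^r f(x)} over the
#' unit interval (the canonical route), or by a truncated triple series
#' expansion of the density in Topp-Leone components (a cross-check only;
#' the series alternates and does not converge for all parameter values,
#' in which case `NA` is returned with a warning).
#'
#' @param r Positive integer moment order.
#' @param theta,beta Positive shape parameters.
#' @param method `"quadrature"` (default) or `"series"`.
#' @param rel.tol Relative tolerance passed to [stats::integrate()].
#' @param max.terms Per-index truncation point of the series expansion.
#' @return The r-th raw moment, a number in (0, 1).
#' @examples
#' mktl_moment(1, theta = 1, beta = 1)
#' @export
mktl_moment <- function(r, theta, beta, method = c("quadrature", "series"),
                        rel.tol = 1e-10, max.terms = 40L) {
  check_shapes(theta, beta)
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r != floor(r))
    abort("`r` must be a positive integer.")
  method <- match.arg(method)
  if (method == "quadrature") {
    qr <- integrate(function(x) x^r * dmktl(x, theta, beta), 0, 1,
                    rel.tol = rel.tol, stop.on.error = FALSE)
    if (qr$message != "OK")
      abort(paste0("moment quadrature did not converge: ", qr$message))
    return(qr$value)
  }
  mktl_moment_series(r, theta, beta, max.terms)
}

# truncated series cross-check: expands exp{-odds^theta}, [1-G]^-(theta(j+1)+1)
# and (2-x)^(bm-1) and integrates term by term against Beta(r+q+bm, 2);
# base R's choose() handles the generalized binomial coefficients
mktl_moment_series <- function(r, theta, beta, max.terms = 40L) {
  q <- 0:max.terms
  total <- 0
  shell_last <- Inf
  for (j in 0:max.terms) {
    shell <- 0
    for (k in 0:max.terms) {
      m <- theta * (j + 1) + k
      bm <- beta * m
      term <- (-1)^(j + k) / factorial(j) * choose(m, k) *
        sum((-1)^q * choose(bm - 1, q) * 2^(bm - q - 1) *
              beta(r + q + bm, 2))
      shell <- shell + term
    }
    total <- total + shell
    if (abs(shell) < 1e-12 && abs(shell_last) < 1e-12) break
    shell_last <- shell
  }
  out <- 2 * beta * total
  if (!is.finite(out) || abs(shell_last) > 1e-6 || out <= 0 || out >= 1) {
    warn("series expansion of the moment did not converge; returning NA.")
    return(NA_real_)
  }
  out
}

#' Log-likelihood and score of the MKTL model
#'
#' `mktl_loglik()` is the exact log-likelihood, the sum of log densities
#' (including the constant \eqn{n\log 2} and \eqn{\sum \log(1-x_i)} terms
#' that drop out of the score).  `mktl_score()` is its analytic gradient
#' \eqn{(\partial\ell/\partial\theta, \partial\ell/\partial\beta)}, derived
#' by direct differentiation of the log density.
#'
#' @param x Numeric vector of observations.  Values outside the open unit
#'   interval make the likelihood zero: `mktl_loglik()` then returns `-Inf`
#'   and `mktl_score()` raises an error.
#' @param theta,beta Positive shape parameters.
#' @return `mktl_loglik()`: a single number (possibly `-Inf`).
#'   `mktl_score()`: a length-2 named vector `c(theta = ..., beta = ...)`.
#' @examples
#' x <- rmktl(50, 3, 0.5, seed = 1)
#' mktl_loglik(x, 3, 0.5)
#' mktl_score(x, 3, 0.5)
#' @export
mktl_loglik <- function(x, theta, beta) {
  check_shapes(theta, beta)
  if (length(x) < 1L) abort("`x` must contain at least one observation.")
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) return(-Inf)
  lg <- mktl_logs(x, theta, beta)
  sum(log(2 * beta * theta) + (beta * theta - 1) * log_g1(x) +
        log1p(-x) - (theta + 1) * lg$l1mG - exp(theta * lg$lodds))
}

#' @rdname mktl_loglik
#' @export
mktl_score <- function(x, theta, beta) {
  check_shapes(theta, beta)
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    abort("all observations must lie strictly inside (0, 1).")
  n <- length(x)
  a <- log_g1(x)                          # log[x(2-x)]
  lg <- mktl_logs(x, theta, beta)
  z_th <- exp(theta * lg$lodds)           # odds^theta
  G_over_1mG <- exp(lg$lG - lg$l1mG)
  d_theta <- n / theta + beta * sum(a) - sum(lg$l1mG) -
    sum(z_th * lg$lodds)
  d_beta <- n / beta + theta * sum(a) +
    (theta + 1) * sum(G_over_1mG * a) -
    theta * sum(z_th * a / (-expm1(lg$lG)))
  c(theta = d_theta, beta = d_beta)
}

#' Plot MKTL density, distribution or hazard curves
#'
#' Convenience ggplot of the model curves for one or more parameter pairs.
#'
#' @param theta,beta Vectors of shape parameters, recycled to equal length;
#'   each pair gives one curve.
#' @param which One of `"pdf"`, `"cdf"`, `"hazard"`.
#' @param n Number of grid points.
#' @return A ggplot object.
#' @examples
#' plot_mktl(theta = c(0.5, 1.5, 3), beta = c(3, 1.5, 0.5))
#' @export
plot_mktl <- function(theta, beta, which = c("pdf", "cdf", "hazard"),
                      n = 301L) {
  which <- match.arg(which)
  pars <- vctrs_recycle(theta, beta)
  grid <- seq(1e-3, 1 - 1e-3, length.out = n)
  fn <- switch(which, pdf = dmktl, cdf = pmktl, hazard = hmktl)
  df <- purrr::map2_dfr(pars$theta, pars$beta, function(th, be) {
    tibble(x = grid, y = fn(grid, th, be),
           pair = sprintf("theta = %g, beta = %g", th, be))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x", y = which, colour = NULL) +
    ggplot2::theme_minimal()
}

# minimal common-length recycling for plot_mktl
vctrs_recycle <- function(theta, beta) {
  len <- max(length(theta), length(beta))
  list(theta = rep_len(theta, len), beta = rep_len(beta, len))
}
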