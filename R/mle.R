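#' Fit the MKTL distribution by maximum likelihood
#'
#' Maximizes the exact MKTL log-likelihood over \eqn{(\theta,\beta)} by
#' quasi-Newton (BFGS) search on the log-parameter scale, which enforces
#' positivity without constraints.  Unless a starting value is supplied the
#' optimizer is multi-started from \eqn{(1,1)} and from the best point of a
#' coarse 5 x 5 log-spaced grid, and the best local optimum is kept.
#' Standard errors come from the inverse observed information (numerical
#' Hessian of the negative log-likelihood at the optimum) and confidence
#' intervals are Wald intervals on the raw parameter scale.
#'
#' @param data A numeric vector of observations in the open unit interval,
#'   or a data frame; for a data frame the column named by `col` (default:
#'   the first numeric column) is used, so fits compose with pipes.
#' @param col Optional column name (string) when `data` is a data frame.
#' @param init Optional starting values, a length-2 numeric vector
#'   `c(theta, beta)`; overrides the multi-start.
#' @param level Confidence level for the Wald intervals (default 0.95).
#' @param gradient `"analytic"` (default) uses [mktl_score()]; `"numeric"`
#'   lets the optimizer difference the objective itself.
#' @param control Passed to [stats::optim()] (merged over sane defaults).
#'
#' @return An object of class `"mktl_mle"`: a list with elements `theta`,
#'   `beta`, `se` (named vector), `vcov` (2 x 2 matrix), `loglik`,
#'   `ci` (tibble with one row per parameter), `converged`, `n_obs`,
#'   `score_norm` (gradient norm at the optimum) and `data`.
#'   Supports [tidy()], [glance()], [autoplot()] and `print()`.
#'
#' @examples
#' x <- covid_mortality()
#' fit <- mktl_fit_mle(x)
#' tidy(fit)
#' glance(fit)
#' @export
mktl_fit_mle <- function(data, col = NULL, init = NULL, level = 0.95,
                         gradient = c("analytic", "numeric"),
                         control = list()) {
  gradient <- match.arg(gradient)
  x <- extract_sample(data, col)
  validate_sample(x, n_min = 3L)
  if (!is.null(init)) {
    if (length(init) != 2L || any(!is.finite(init)) || any(init <= 0))
      abort("`init` must be two positive finite numbers c(theta, beta).")
  }

  # line searches can overshoot to exp(lp) = Inf; treat such points as
  # infinitely bad instead of erroring inside optim
  nll <- function(lp) {
    p <- exp(lp)
    if (any(!is.finite(p)) || any(p <= 0)) return(.Machine$double.xmax)
    -mktl_loglik(x, p[1], p[2])
  }
  gr <- if (gradient == "analytic") {
    function(lp) {
      p <- exp(lp)
      if (any(!is.finite(p)) || any(p <= 0)) return(c(0, 0))
      g <- -mktl_score(x, p[1], p[2]) * p   # chain rule to the log scale
      g[!is.finite(g)] <- 0
      g
    }
  } else NULL
  ctl <- modifyList(list(maxit = 500L, reltol = 1e-12), control)

  starts <- if (!is.null(init)) list(log(init)) else mle_starts(x)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, nll, gr = gr, method = "BFGS", control = ctl),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) abort("optimization failed from every starting value.")

  est <- exp(best$par)
  H <- optimHess(est, function(p) {
    if (any(p <= 0)) return(Inf)
    -mktl_loglik(x, p[1], p[2])
  })
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  dimnames(V) <- list(c("theta", "beta"), c("theta", "beta"))
  se <- sqrt(pmax(diag(V), 0))
  score <- mktl_score(x, est[1], est[2])

  fit <- structure(list(
    theta = unname(est[1]),
    beta = unname(est[2]),
    se = se,
    vcov = V,
    loglik = -best$value,
    converged = best$convergence == 0 && all(is.finite(se)),
    n_obs = length(x),
    score_norm = sqrt(sum(score^2)),
    level = level,
    data = x
  ), class = "mktl_mle")
  fit$ci <- wald_ci(fit, level)
  fit
}

# starting values: (1,1) plus the best of a coarse log-spaced grid
mle_starts <- function(x) {
  grid <- expand.grid(lt = log(c(0.25, 1, 4, 16, 64)) / 2,
                      lb = log(c(0.25, 1, 4, 16, 64)) / 2)
  ll <- mapply(function(lt, lb) mktl_loglik(x, exp(lt), exp(lb)),
               grid$lt, grid$lb)
  best <- which.max(ll)
  list(c(0, 0), c(grid$lt[best], grid$lb[best]))
}

#' Wald confidence intervals for an MKTL maximum-likelihood fit
#'
#' Computes `estimate +/- z * SE` per parameter, with
#' `z = qnorm((1 + level) / 2)`.
#'
#' @param fit An `"mktl_mle"` object.
#' @param level Confidence level in (0, 1).
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mktl_mle"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    abort("`level` must be a single number strictly inside (0, 1).")
  z <- qnorm((1 + level) / 2)
  est <- c(theta = fit$theta, beta = fit$beta)
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(fit$se),
    conf.low = unname(est - z * fit$se),
    conf.high = unname(est + z * fit$se)
  )
}

#' @export
print.mktl_mle <- function(x, ...) {
  cat("MKTL maximum-likelihood fit (n =", x$n_obs, ")\n")
  cat(sprintf("  theta = %.4f (SE %.4f)\n", x$theta, x$se["theta"]))
  cat(sprintf("  beta  = %.4f (SE %.4f)\n", x$beta, x$se["beta"]))
  cat(sprintf("  log-likelihood = %.4f, converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}

#' @rdname mktl_fit_mle
#' @param x,object An `"mktl_mle"` object.
#' @param ... Unused.
#' @method tidy mktl_mle
#' @export
tidy.mktl_mle <- function(x, ...) {
  x$ci
}

#' @rdname mktl_fit_mle
#' @method glance mktl_mle
#' @export
glance.mktl_mle <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 4,
    BIC = -2 * x$loglik + 2 * log(x$n_obs),
    nobs = x$n_obs,
    converged = x$converged,
    score.norm = x$score_norm
  )
}

#' @rdname mktl_fit_mle
#' @method autoplot mktl_mle
#' @export
autoplot.mktl_mle <- function(object, ...) {
  grid <- seq(1e-3, 1 - 1e-3, length.out = 301)
  dens <- tibble(x = grid, y = dmktl(grid, object$theta, object$beta))
  obs <- tibble(x = object$data)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = max(8L, ceiling(sqrt(object$n_obs))),
                            fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = dens, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "#2166ac", linewidth = 0.9) +
    ggplot2::labs(x = "x", y = "density",
                  title = sprintf("MKTL fit: theta = %.3f, beta = %.3f",
                                  object$theta, object$beta)) +
    ggplot2::theme_minimal()
}

# ---- shared sample handling ----

# accept a bare numeric vector or a data frame (first numeric column, or
# the column named by `col`)
extract_sample <- function(data, col = NULL) {
  if (is.data.frame(data)) {
    if (!is.null(col)) {
      if (!col %in% names(data)) abort(paste0("column `", col, "` not found."))
      x <- data[[col]]
    } else {
      num <- vapply(data, is.numeric, logical(1))
      if (!any(num)) abort("`data` has no numeric column.")
      x <- data[[which(num)[1]]]
    }
  } else {
    x <- data
  }
  if (!is.numeric(x)) abort("observations must be numeric.")
  as.numeric(x)
}

validate_sample <- function(x, n_min = 1L) {
  if (length(x) < n_min)
    abort(paste0("at least ", n_min, " observations are required."))
  bad <- which(!is.finite(x) | x <= 0 | x >= 1)
  if (length(bad))
    abort(paste0("observations must lie strictly inside (0, 1); offending ",
                 "positions: ", paste(head(bad, 5L), collapse = ", "),
                 if (length(bad) > 5L) ", ..."))
  if (length(unique(x)) == 1L && length(x) > 1L)
    abort("degenerate sample: all observations are identical.")
  invisible(x)
}
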