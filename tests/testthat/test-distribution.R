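test_that("Topp-Leone baseline CDF matches closed-form values and is monotone", {
  expect_equal(ptl(0.5, beta = 1), 0.75)
  # [0.1 * 1.9]^0.5 = sqrt(0.19)
  expect_equal(ptl(0.1, beta = 0.5), sqrt(0.19), tolerance = 1e-12)
  expect_lt(abs(ptl(1 - 1e-9, beta = 2.5) - 1), 1e-8)
  g <- ptl(seq(0.01, 0.99, by = 0.01), beta = 1.7)
  expect_true(all(diff(g) > 0))
  expect_error(ptl(1.2, beta = 1), "unit interval")
  expect_error(ptl(0.5, beta = -1), "positive")
})

test_that("CDF takes its closed-form values and clamps outside the support", {
  # G = 0.75 at x = 0.5 with beta = 1, so F = 1 - exp(-(0.75/0.25)^1)
  expect_equal(pmktl(0.5, 1, 1), 1 - exp(-3), tolerance = 1e-14)
  expect_equal(pmktl(c(-1, 0, 1, 2), 2, 3), c(0, 0, 1, 1))
  # quadrature of the density is an independent route to the same value
  quad <- integrate(function(x) dmktl(x, 3.7670, 0.7145), 0, 0.198,
                    rel.tol = 1e-12)$value
  expect_equal(pmktl(0.198, 3.7670, 0.7145), quad, tolerance = 1e-9)
  expect_equal(quad, 0.5166525, tolerance = 1e-6)
})

test_that("density matches finite differences of the CDF and integrates to 1", {
  expect_equal(dmktl(0.5, 1, 1), 16 * exp(-3), tolerance = 1e-12)
  expect_equal(dmktl(c(0, 1), 1, 1), c(0, 0))
  h <- 1e-6
  for (p in list(c(0.5, 3), c(1.5, 1.5), c(3, 0.5))) {
    for (x0 in c(0.1, 0.4, 0.8)) {
      fd <- (pmktl(x0 + h, p[1], p[2]) - pmktl(x0 - h, p[1], p[2])) / (2 * h)
      expect_equal(dmktl(x0, p[1], p[2]), fd, tolerance = 1e-6)
    }
  }
  for (p in par_grid) {
    mass <- integrate(function(x) dmktl(x, p[1], p[2]), 0, 1,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
  }
})

test_that("survival complements the CDF and matches its closed form", {
  expect_equal(smktl(0.5, 1, 1), exp(-3), tolerance = 1e-14)
  expect_equal(smktl(0.1, 3, 0.5),
               exp(-(sqrt(0.19) / (1 - sqrt(0.19)))^3), tolerance = 1e-12)
  xs <- seq(0.02, 0.98, length.out = 49)
  for (p in par_grid) {
    expect_lt(max(abs(pmktl(xs, p[1], p[2]) + smktl(xs, p[1], p[2]) - 1)),
              1e-12)
  }
  expect_lt(abs(smktl(1e-12, 2, 2) - 1), 1e-10)
})

test_that("hazard equals density over survival and rejects the boundary", {
  expect_equal(hmktl(0.5, 1, 1), 16, tolerance = 1e-12)
  expect_equal(hmktl(0.1, 3, 0.5), 11.62211, tolerance = 1e-4)
  xs <- seq(0.01, 0.99, length.out = 100)
  for (p in list(c(3, 0.5), c(1.5, 1.5), c(0.5, 3))) {
    # away from the upper boundary, where the survival factor has not yet
    # underflown and the ratio is numerically meaningful
    keep <- smktl(xs, p[1], p[2]) > 1e-12
    expect_gt(sum(keep), 25)
    hr <- hmktl(xs[keep], p[1], p[2])
    ratio <- dmktl(xs[keep], p[1], p[2]) / smktl(xs[keep], p[1], p[2])
    expect_lt(max(abs(hr / ratio - 1)), 1e-10)
  }
  expect_error(hmktl(0, 1, 1), "inside")
  expect_error(hmktl(1, 1, 1), "inside")
})

test_that("hazard shapes cover monotone and bathtub regimes", {
  xs <- seq(0.05, 0.95, length.out = 181)
  expect_true(all(diff(hmktl(xs, 3, 0.5)) > 0))           # increasing
  d <- diff(hmktl(xs, 0.3, 0.5))                          # bathtub
  expect_true(d[1] < 0 && d[length(d)] > 0)
})

test_that("quantile function inverts the CDF", {
  # frozen from a bisection oracle on the CDF
  expect_equal(qmktl(0.5, 1, 1), 0.23148448, tolerance = 1e-7)
  bis <- uniroot(function(x) pmktl(x, 2.2, 0.8) - 0.31, c(1e-9, 0.999),
                 tol = 1e-13)$root
  expect_equal(qmktl(0.31, 2.2, 0.8), bis, tolerance = 1e-9)
  u <- seq(0.01, 0.99, by = 0.01)
  for (p in list(c(3, 0.5), c(1.5, 1.5), c(0.5, 3))) {
    expect_lt(max(abs(pmktl(qmktl(u, p[1], p[2]), p[1], p[2]) - u)), 1e-10)
    expect_true(all(diff(qmktl(u, p[1], p[2])) > 0))
  }
  expect_lt(qmktl(1e-10, 1, 1), 1e-4)
  # the upper limit is approached monotonically (slowly: the modified Kies
  # odds transform stretches the upper tail)
  near1 <- qmktl(1 - 10^-(6:14), 1, 1)
  expect_true(all(diff(near1) > 0))
  expect_true(all(near1 < 1))
  expect_error(qmktl(0, 1, 1), "inside")
  expect_error(qmktl(1, 1, 1), "inside")
})

test_that("random generation is seed-reproducible and model-consistent", {
  a <- rmktl(100, 3, 0.5, seed = 42)
  b <- rmktl(100, 3, 0.5, seed = 42)
  expect_identical(a, b)
  expect_true(all(a > 0 & a < 1))
  x <- rmktl(5000, 3, 0.5, seed = 7)
  pit <- pmktl(x, 3, 0.5)
  expect_gt(suppressWarnings(ks.test(pit, "punif")$p.value), 0.01)
})

test_that("moments are consistent with Monte Carlo and basic inequalities", {
  # oracle: mean of 1e6 inversion draws at (1,1) is 0.24210 +/- 0.00045
  expect_equal(mktl_moment(1, 1, 1), 0.2421278, tolerance = 1e-6)
  set.seed(5)
  mc <- mean(rmktl(2e5, 3, 0.5))
  expect_equal(mktl_moment(1, 3, 0.5), mc, tolerance = 0.01)
  for (p in par_grid[c(1, 5, 9)]) {
    m1 <- mktl_moment(1, p[1], p[2])
    m2 <- mktl_moment(2, p[1], p[2])
    m3 <- mktl_moment(3, p[1], p[2])
    expect_gte(m2, m1^2)          # nonnegative variance
    expect_lt(m2, m1)             # E[X^r] decreasing on (0,1) support
    expect_lt(m3, m2)
  }
})

test_that("the series route either agrees with quadrature or reports failure", {
  for (p in list(c(1, 1), c(3, 0.5), c(0.5, 1.5))) {
    out <- withCallingHandlers(
      mktl_moment(1, p[1], p[2], method = "series"),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.finite(out))
      expect_equal(out, mktl_moment(1, p[1], p[2]), tolerance = 1e-4)
    else
      expect_true(is.na(out))
  }
})

test_that("log-likelihood is the sum of log densities and flags bad input", {
  expect_equal(mktl_loglik(0.5, 1, 1), log(16) - 3, tolerance = 1e-12)
  set.seed(8)
  x <- rmktl(20, 1.5, 1.5)
  expect_equal(mktl_loglik(x, 2, 0.9), sum(dmktl(x, 2, 0.9, log = TRUE)),
               tolerance = 1e-12)
  expect_identical(mktl_loglik(c(x, 1.5), 2, 0.9), -Inf)
  # the mortality fixture is maximized at the fitted parameters
  ll0 <- mktl_loglik(covid, 3.7670, 0.7145)
  for (d in list(c(0.05, 0), c(-0.05, 0), c(0, 0.05), c(0, -0.05))) {
    expect_lt(mktl_loglik(covid, 3.7670 + d[1], 0.7145 + d[2]), ll0)
  }
})
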