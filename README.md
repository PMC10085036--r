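# mktl

Tools for the **modified Kies Topp-Leone (MKTL) distribution**, a
two-parameter lifetime model for data bounded in the open unit interval —
daily mortality rates, proportions, normalized failure times. The model
inserts the Topp-Leone CDF $G(x;\beta) = [x(2-x)]^\beta$ into the modified
Kies generator:

$$F(x;\theta,\beta) = 1 - \exp\left\{-\left[\frac{G(x;\beta)}{1 -
G(x;\beta)}\right]^\theta\right\}, \qquad 0 < x < 1,\ \theta,\beta > 0.$$

The odds transform gives the family increasing, decreasing and
bathtub-shaped hazard rates, which plain bounded-support models such as
Topp-Leone cannot reach. The package is aimed at statisticians and
epidemiologists fitting bounded rate data and comparing estimators.

It provides:

* `dmktl()`, `pmktl()`, `qmktl()`, `rmktl()`, `smktl()`, `hmktl()`,
  `mktl_moment()` — the distribution itself, with log-space evaluation,
  closed-form inversion sampling and seed-stable generation;
* `mktl_fit_mle()` — maximum likelihood with analytic score, multi-start
  BFGS on the log scale, observed-information standard errors and Wald
  intervals; broom-style `tidy()` / `glance()` and `autoplot()`;
* `mktl_fit_bayes()` — gamma priors elicited by moment matching
  (`mktl_elicit_prior()`), random-walk Metropolis-Hastings sampling,
  posterior-mean estimates and Chen-Shao HPD intervals (`hpd_interval()`);
* `fuzzy_band()`, `fuzzy_reliability()` — fuzzy reliability under a linear
  ramp membership function with gamma-cuts, in both the interval and the
  membership-weighted variants;
* `mktl_gof()` — Kolmogorov-Smirnov (with exact small-sample p-value),
  Cramer-von Mises and Anderson-Darling statistics through the
  probability integral transform;
* `mktl_mc_study()`, `mktl_mc_fuzzy()` — a seeded Monte Carlo harness
  reporting bias, MSE, interval bounds and coverage per estimator;
* `covid_mortality()` — the packaged 27-day Saudi Arabia COVID-19
  mortality-rate series used in the worked example.

## Worked example

```r
library(mktl)

x <- covid_mortality()      # 27 daily mortality rates, all in (0, 1)
fit <- mktl_fit_mle(x)
fit
#> MKTL maximum-likelihood fit (n = 27 )
#>   theta = 3.7666 (SE 0.5535)
#>   beta  = 0.7144 (SE 0.0277)
#>   log-likelihood = 44.1489, converged: TRUE

tidy(fit)
#> # A tibble: 2 × 5
#>   term  estimate std.error conf.low conf.high
#>   <chr>    <dbl>     <dbl>    <dbl>     <dbl>
#> 1 theta    3.77     0.553     2.68      4.85
#> 2 beta     0.714    0.0277    0.660     0.769

mktl_gof(fit)
#> # A tibble: 1 × 5
#>      ks ks_pvalue      W     A     n
#>   <dbl>     <dbl>  <dbl> <dbl> <int>
#> 1 0.125     0.743 0.0536 0.387    27

fuzzy_reliability(fit$theta, fit$beta, fuzzy_band(0.12, 0.25))
#> # A tibble: 3 × 4
#>   gamma cut_lifetime reliability variant
#>   <dbl>        <dbl>       <dbl> <chr>
#> 1   0.3        0.159       0.157 interval
#> 2   0.6        0.198       0.431 interval
#> 3   0.9        0.237       0.736 interval

mktl_fit_bayes(x, seed = 1)
#> MKTL Bayesian fit (random-walk Metropolis-Hastings)
#>   10000 iterations, 2000 burn-in, acceptance rate 0.241
#>   posterior mean theta = 3.7273 (sd 0.3922)
#>   posterior mean beta  = 0.7158 (sd 0.0195)
```

Reading the output: the fitted shapes $(\hat\theta, \hat\beta) \approx
(3.77, 0.71)$ put the series in the unimodal, right-tailed part of the
family; the KS distance 0.125 with p-value 0.74 says the fitted CDF is
fully compatible with the empirical one; and the fuzzy reliability column
gives the probability that a day's rate falls between the lower membership
knot (0.12) and the gamma-cut lifetime — rising from 0.16 at
$\gamma = 0.3$ to 0.74 at $\gamma = 0.9$ as the cut interval widens.

The hazard shapes and the fit itself can be inspected graphically with
`plot_mktl(theta, beta, which = "hazard")`, `autoplot(fit)` and
`autoplot(bayes_fit)` (MCMC traces).

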