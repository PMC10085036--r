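---
title: "Methods behind the mktl package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the mktl package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mktl)
```

## The model

The modified Kies Topp-Leone (MKTL) distribution is a two-parameter
lifetime model on the open unit interval, built by inserting the
Topp-Leone CDF

$$G(x;\beta) = [x(2-x)]^\beta, \qquad 0 < x < 1,$$

into the modified Kies generator:

$$F(x;\theta,\beta) = 1 - \exp\!\left\{-\left[\frac{G(x;\beta)}
  {1-G(x;\beta)}\right]^{\theta}\right\}.$$

Both parameters are dimensionless shapes. The odds transform
$G/(1-G)$ stretches the upper tail, so the family covers increasing,
decreasing and bathtub-shaped hazard rates - the main advantage over the
plain Topp-Leone model, whose hazard is far more rigid. Bounded rates
such as daily mortality proportions are the intended use case.

Because $G \to 1$ as $x \to 1$, the odds ratio overflows long before
double precision runs out. All internal evaluations therefore work in
log space: $\log G = \beta \log[x(2-x)]$, with $\log[x(2-x)]$ computed
as `log1p(-(1-x)^2)` above $x = 0.5$ to avoid cancellation, and
$\log(1-G)$ as `log(-expm1(log G))`. The quantile function is the exact
inverse

$$x(u) = 1 - \sqrt{1 - G_u^{1/\beta}}, \qquad
  G_u = \frac{w}{1+w}, \quad w = [-\log(1-u)]^{1/\theta},$$

validated against bisection on the CDF; random variates are inversion
samples of seeded uniforms, which keeps every simulation reproducible
from a single integer seed.

## Moments

`mktl_moment()` integrates $x^r f(x)$ by adaptive quadrature
(relative tolerance $10^{-10}$); this is the canonical route. A
term-by-term series expansion of the density in Topp-Leone components is
also provided (`method = "series"`), but it is documented as a
cross-check only and guarded: each mixture term carries a factor
$[1-G]^{-(\theta(j+1)+1)} \sim (1-x)^{-2\theta(j+1)-2}$ near $x = 1$
against a single $(1-x)$ from the density, so every term's integral over
the support is infinite and the rearranged series has no finite limit in
double precision. When the guard detects non-convergence the function
returns `NA` with a warning rather than a misleading number.

## Maximum likelihood

`mktl_fit_mle()` maximizes the exact log-likelihood - the sum of log
densities, including the parameter-free $n\log 2$ and
$\sum \log(1-x_i)$ terms, so the reported value is comparable across
models. Design choices:

* **Parameterization.** BFGS on $(\log\theta, \log\beta)$, which makes
  the positivity constraint vanish. A raw-scale Newton-type search
  reaches the same stationary point; the optimum is certified by the
  first-order condition (score norm below $10^{-4}$) rather than by the
  optimizer's internal status alone.
* **Multi-start.** From $(1,1)$ and from the best point of a coarse
  $5\times5$ log-spaced grid, keeping the better local optimum. Line
  searches that overshoot to infinite parameters are treated as
  infinitely bad points, not errors.
* **Gradients.** The analytic score is a clean re-derivation of
  $\partial\ell/\partial\theta$ and $\partial\ell/\partial\beta$ from
  the log density; central finite differences of the log-likelihood act
  as the arbiter in the test suite (relative agreement $10^{-6}$), and
  `gradient = "numeric"` switches the optimizer to differencing.
* **Uncertainty.** Standard errors come from the inverse observed
  information, a central-difference Hessian of the negative
  log-likelihood at the optimum; intervals are Wald,
  $\hat\vartheta \pm z_{(1+\text{level})/2}\,\mathrm{SE}$.
* **Degenerate input.** Fewer than three observations, constant
  samples, and values touching 0 or 1 are rejected with explicit
  errors; the likelihood is $-\infty$ outside the support.

## Bayesian estimation

Independent gamma priors $\theta \sim \Gamma(\varphi_1, D_1)$,
$\beta \sim \Gamma(\varphi_2, D_2)$ are elicited by moment matching a
set of $B$ estimate replicates: $\varphi_j = \bar\Omega_j^2 / s_j^2$ and
$D_j = \bar\Omega_j / s_j^2$, so the prior mean and variance reproduce
the replicate mean and variance exactly.

The replicates themselves can be generated two ways, and the choice
matters at small $n$:

* `method = "normal"` (default) draws them from the asymptotic law
  $N(\hat\Theta, \hat V)$ of the estimator - literally from the
  estimate and its variance-covariance matrix. The prior is then
  centered at the fitted values.
* `method = "bootstrap"` refits the model to parametric-bootstrap
  resamples. At $n$ in the twenties the bootstrap distribution of
  $\hat\theta$ inherits the estimator's upward small-sample bias, so
  the elicited prior (and hence the posterior mean) is shifted above
  the MLE by a non-negligible amount. We keep this route available but
  do not default to it.

The posterior is sampled by a bivariate Gaussian random-walk
Metropolis-Hastings chain started at the MLE. The `"auto"` proposal
covariance is $\hat V \cdot 2.4^2/2$, the classical scaling for a
two-dimensional random walk; proposals with a non-positive component
are rejected (zero prior mass). Default chain length 10000 with 2000
burn-in gives acceptance rates around 0.2-0.3 on samples of this size
and posterior means stable to about $\pm 0.03$ across seeds; both
numbers are recorded in the fitted object. Point estimates are
posterior means (the Bayes rule under squared-error loss), and
intervals are Chen-Shao highest-posterior-density windows: sort the
$M$ draws, slide a window of $\lceil \text{level}\cdot M\rceil$
consecutive order statistics, keep the narrowest (leftmost on ties).

One caveat is documented rather than hidden: a prior elicited from the
same data it is combined with uses the data twice, so the posterior
contracts below the sampling variability of the MLE and its credible
intervals cover the truth at less than the nominal rate in repeated
sampling. The test suite therefore checks HPD coverage under a fixed
weakly-informative prior, and checks the elicited-prior pipeline
against the fitted values it is designed to reproduce.

## Fuzzy reliability

The fuzzy machinery uses a linear ramp membership function with knots
$0 \le t_1 < t_2 < 1$: $\mu(x) = 0$ below $t_1$, $(x-t_1)/(t_2-t_1)$
between the knots, 1 above. A cut level $\gamma \in [0,1]$ maps to the
lifetime $x(\gamma) = t_1 + \gamma(t_2-t_1)$.

Two reliability variants are exposed because the defining integral and
the values conventionally reported disagree:

* `"interval"` (default): the plain probability mass
  $F(x(\gamma)) - F(t_1) = S(t_1) - S(x(\gamma))$, computed from
  survival values for numerical stability. At $\gamma = 1$ this equals
  the closed-form difference of survival values at the knots.
* `"weighted"`: the membership-weighted integral
  $\int_{t_1}^{x(\gamma)} \mu(x) f(x)\,dx$ by adaptive quadrature
  (absolute tolerance $10^{-9}$). Since $\mu \le 1$ on the range, the
  weighted value never exceeds the interval value.

The interval variant is the default because it is the quantity that
published fuzzy-reliability tables for this model actually contain; the
weighted variant implements the membership-weighted definition
literally. Both are 0 at $\gamma = 0$ and nondecreasing in $\gamma$.

## Goodness of fit

`mktl_gof()` feeds the sorted data through the fitted CDF (probability
integral transform) and computes the one-sample Kolmogorov-Smirnov
distance, the Cramer-von Mises statistic
$W = 1/(12n) + \sum_i (u_{(i)} - (2i-1)/(2n))^2$ and the
Anderson-Darling statistic
$A = -n - n^{-1}\sum_i (2i-1)[\ln u_{(i)} + \ln(1-u_{(n+1-i)})]$.
Both formulas are cross-checked in the tests against the independent
`goftest` implementations. The statistics are evaluated at the fitted
parameters - the convention used when ranking candidate models on one
data set - so the KS p-value (exact small-sample form via
`stats::ks.test`) is approximate in the usual fit-statistics sense, and
no p-values are attached to $W$ or $A$. Ties in the data produce a
warning, not an error.

## The Monte Carlo harness

`mktl_mc_study()` implements the estimator-comparison experiment:
replicate samples are drawn by inversion, fitted by maximum likelihood
and optionally by the Bayesian pipeline, and each cell reports average
bias, mean squared error, mean interval bounds and coverage
probability, for the parameters and for the survival and hazard
functions at fixed time points (delta-method intervals for the MLE,
HPD intervals of the transformed draws for the Bayesian method).
`mktl_mc_fuzzy()` applies the same machinery to interval-variant fuzzy
reliability over a band, where the truth is the fuzzy reliability at
the true parameters; the $\gamma = 0$ cell is identically zero by
construction.

Seed management: one master seed draws a vector of per-replicate
sub-seeds, so the whole table is reproducible and the Bayesian method
sees exactly the same samples as the MLE. Failed fits are dropped and
counted, and a cell with more than 5% failures is flagged. Because
per-replicate MCMC is expensive, Bayesian cells default to a seeded
subsample of at most 500 replicate streams (`bayes_reps`).

Problem sizes: the headline experiment design uses 5000 replicates per
cell; the packaged tests and the acceptance script run 2000 replicates
for the maximum-likelihood cells (Monte Carlo standard errors scale
with $1/\sqrt{\text{reps}}$, so aggregates are stable to two to three
significant figures at that size) and smaller, explicitly-seeded runs
for the Bayesian and fuzzy cells.

What the generator does and does not emulate: samples are i.i.d. draws
from the model itself, which is exactly the premise of the simulation
design - it measures estimator behaviour under a correctly specified
model. Real mortality-rate series are serially dependent and possibly
non-stationary; passing simulation checks therefore says nothing about
robustness to dependence or misspecification, and the goodness-of-fit
module is the tool that addresses model adequacy on real data.

## Numerical conventions

* Inversions (quantile/CDF round trips) are accurate to $10^{-10}$;
  quadrature tolerances are $10^{-8}$ for normalization checks and
  $10^{-9}$ (absolute) for membership-weighted integrals - all well
  inside double precision for these smooth integrands.
* The CDF clamps to 0 and 1 outside the support and the density is 0
  there; the hazard raises a domain error instead, because $f/S$ is
  undefined off the support.
* The hazard/density/survival identity is only testable where the
  survival factor has not underflown ($S > 10^{-12}$); beyond that the
  ratio is 0/0 in double precision while the hazard itself remains
  finite and monotone.
* HPD ties resolve to the leftmost narrowest window; tied observations
  in the PIT are kept with a stable sort and a warning.

## Limitations

* The model lives on $(0,1)$; data on other bounded scales must be
  rescaled by the user, and values touching the boundary are rejected
  rather than nudged.
* Closed forms for incomplete moments, entropy and order statistics
  are not provided; the series route to moments is a guarded
  cross-check, not a working evaluator.
* The elicited-prior Bayesian pipeline is a reproduction of a
  published procedure, with the double-use-of-data caveat described
  above.
* KS/W/A are fit statistics at estimated parameters; for formal
  hypothesis testing their null distributions would need parametric
  bootstrap calibration, which is out of scope.
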