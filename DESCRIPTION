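Package: mktl
Title: Modified Kies Topp-Leone Distribution for Bounded Lifetime Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density, distribution, quantile, random generation, hazard and
    moment functions for the two-parameter modified Kies Topp-Leone (MKTL)
    lifetime distribution on the unit interval, together with maximum
    likelihood and Bayesian (random-walk Metropolis-Hastings) estimation,
    fuzzy reliability under a linear ramp membership function with gamma-cuts,
    goodness-of-fit statistics (Kolmogorov-Smirnov, Cramer-von Mises,
    Anderson-Darling) computed through the probability integral transform,
    and a seeded Monte Carlo harness reporting bias, mean squared error,
    confidence-interval bounds and coverage probability. Fitted objects
    support broom-style tidy() and glance() and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    goftest,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
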