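# shared fixtures built in code

covid <- covid_mortality()

# parameter pairs spanning increasing, decreasing and bathtub hazard shapes
par_grid <- list(
  c(0.5, 0.5), c(0.5, 1.5), c(0.5, 3),
  c(1.5, 0.5), c(1.5, 1.5), c(1.5, 3),
  c(3, 0.5), c(3, 1.5), c(3, 3)
)

# reference MLE for the mortality fixture, computed once per test run
covid_fit <- mktl_fit_mle(covid)
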