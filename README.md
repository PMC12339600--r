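# itcnet

Amortized and likelihood-based inference for models of intertemporal
choice.

## The problem

Delay discounting — how quickly a reward loses subjective value as its
receipt is pushed into the future — is one of the most widely used
behavioral markers of impulsivity, with applications across addiction,
mental health and decision research. It is typically measured with
binary choices between a smaller-sooner (SS) and a larger-later (LL)
payoff, most famously the fixed 27-item monetary choice questionnaire
(MCQ), and summarized by fitting cognitive models to the choices.

itcnet implements the full workflow for three standard models and two
inference routes, for researchers who want model-based estimates of
discounting without writing samplers or training code:

* **Models.** Hyperbolic discounting `v = x / (1 + k t)` with a
  logistic choice rule `Pr(LL) = 1 / (1 + exp(-m (v_LL - v_SS)))`;
  the hyperboloid (modified Rachlin) extension with time-sensitivity
  exponent `s`, `v = x / (1 + (k t)^s)` (payoff-scaled) or
  `v = 1 / (1 + (k t)^s)` (normalized, the canonical generative
  form); and the attribute-wise direct-difference model
  `d = w (x1^u - x2^u) - (1 - w) (t1^v - t2^v)` with endogenous noise
  `sigma^2 = w(1-w)(a+b)^2` and `Pr(LL) = pnorm(d / sigma)`.
* **Amortized inference.** Simulation-inversion neural networks
  (tanh 100/66/33 feed-forward for the questionnaire's 27-bit input;
  an LSTM(150) sequence network for designs with 20–200 arbitrary
  trials) trained on synthetic participants to return parameter
  estimates, posterior model probabilities, and — via Monte-Carlo
  dropout — full joint posterior samples, in milliseconds per
  participant once trained.
* **Likelihood benchmark.** Adaptive Metropolis MCMC (individual and
  hierarchical), MAP/posterior-mean extraction, split-Rhat
  diagnostics, and model comparison by maximized log-likelihood, AIC,
  BIC, DIC and WAIC, with confusion matrices and calibration curves
  to score everything against known ground truth.

All networks and samplers are implemented in the package (C++ via
Rcpp/RcppArmadillo); no external deep-learning runtime is required.

## Worked example

Simulate a participant with known parameters, then recover them by
MCMC and compare the three models:

```r
library(itcnet)

design <- generate_variable_design(seed = 5, n_trials = 200)
truth <- list(k = exp(-3), m = exp(2))        # log k = -3, log m = 2
choices <- simulate_participant("hyperbolic", truth, design, seed = 9)

fit <- fit_individual("hyperbolic", design, choices,
                      config = mcmc_config(n_chains = 2, n_iter = 2000,
                                           n_burn = 800, seed = 2))
fit
#> <itc_fit> hyperbolic, 2400 draws, 200 trials
#>       log_k log_m
#> map  -2.914 1.622
#> mean -2.939 1.506
#> rhat  1.011 1.022
```

The posterior mean of `log k` (-2.94) recovers the generating value
(-3) well inside the posterior spread, and both split-Rhat values sit
near 1, so the two chains agree. `map` is the stored draw with the
highest joint log-density.

Model comparison on the same data:

```r
ll <- vapply(model_labels(), function(mo) {
  f <- fit_individual(mo, design, choices,
                      config = mcmc_config(n_chains = 2, n_iter = 2000,
                                           n_burn = 800, seed = 3))
  max(f$loglik)
}, numeric(1))
bics <- vapply(model_labels(), function(mo)
  information_criteria(ll[[mo]], n_params(mo), 200)[["BIC"]], numeric(1))
round(bic_posterior_probs(bics), 3)
#> direct_difference        hyperbolic       hyperboloid
#>                 0                 1                 0
```

The BIC-approximated posterior model probabilities identify the true
generative (hyperbolic) model.

For amortized inference, train networks once on synthetic data
(`generate_dataset()` + `train_estimator()` / `train_classifier()`),
then `estimate()`, `classify()` or `sample_posterior()` map new data
to results in a single forward pass. `run_model_recovery()` scores
any of the inference methods against ground truth, and a command-line
wrapper (`inst/cli/itcnet`) exposes the whole pipeline as
subcommands (`simulate`, `train-classifier`, `fit-mcmc`,
`benchmark`, ...).

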