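---
title: "Models and methods behind itcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind itcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

itcnet estimates and compares cognitive models of intertemporal choice
— decisions between a smaller-sooner (SS) and a larger-later (LL)
monetary payoff — by two complementary routes: *amortized inference*,
where neural networks trained on simulated participants map observed
choices straight to parameters or model probabilities, and
*likelihood-based Bayesian inference* by MCMC. This vignette documents
the models, the generative assumptions behind the synthetic data, the
network and sampler design choices, and the limits of what the bundled
experiments can show.

## The three choice models

All models predict the probability that a participant chooses the
larger-later option of a pair (`x_ss` now-or-soon vs `x_ll` after a
longer delay, payoffs in currency units, delays in days).

**Hyperbolic discounting.** Subjective value decays hyperbolically
with delay, `v(x, t) = x / (1 + k t)`. The discounting rate `k`
(1/days) indexes impulsivity. Choice follows a logistic rule on the
value difference `d = v(LL) - v(SS)`:
`Pr(LL) = 1 / (1 + exp(-d m))`. We implement the slope `m` literally:
larger `m` makes choices more deterministic, smaller `m` more random.
(Verbal descriptions of this parameter sometimes run the other way;
the equation is unambiguous and the implementation follows it.)

**Hyperboloid (modified Rachlin).** A time-sensitivity exponent `s`
enters as `(k t)^s`, keeping the units of `k` at 1/days for every `s`
(the "muddled units" correction). The package implements two
numerator conventions, both exposed through
`hyperboloid_value(..., payoff_scaled =)`:

* the *normalized* form `v = 1 / (1 + (k t)^s)`, in which value lives
  on a unit scale and payoffs do not enter the comparison. This is the
  canonical generative `"hyperboloid"` model of the package: the
  bundled recovery and model-comparison experiments are calibrated
  under it, and its signature — choices driven by delays alone — is
  what makes the model family sharply distinguishable from the
  payoff-sensitive families in classification experiments.
* the *payoff-scaled* form `v = x / (1 + (k t)^s)`, which reduces
  exactly to the hyperbolic model at `s = 1` and scales with payoff.
  This is the natural likelihood competitor in nested model
  comparison, and it is the form the likelihood benchmark fits
  (`fit_individual(..., hyperboloid_form = "payoff_scaled")`,
  the default of `run_model_recovery()`'s criterion stage). Fitting
  the nesting form while simulating from the normalized form is a
  deliberate asymmetry: it is the configuration under which the
  benchmark's reference behavior (the BIC's strong preference for the
  two-parameter hyperbolic model, the hyperbolic-to-hyperboloid
  confusions of deviance-based criteria) arises.

**Direct difference.** An attribute-wise model: instead of valuing
each option, the decision maker weighs payoff differences against
delay differences, `d = w (x1^u - x2^u) - (1 - w) (t1^v - t2^v)`,
with payoff sensitivity `u`, delay sensitivity `v`, and attention
weight `w` in [0, 1]. Choice variability is endogenous: attention
fluctuates trial to trial, so the evidence is normal with
`sigma^2 = w a^2 + (1 - w) b^2 - d^2` (algebraically
`w (1 - w) (a + b)^2`, hence never negative; rounding residue is
clamped at zero) and `Pr(LL) = pnorm(d / sigma)`. At `w = 0` or
`w = 1` the variance vanishes and the rule becomes a step function
(probability 0.5 exactly at indifference), so simulation never halts.

Log-likelihoods are Bernoulli sums with probabilities clamped to
`[1e-12, 1 - 1e-12]`, so a single surprising choice under a
deterministic prediction costs about 27.6 log-units rather than
infinity.

## Synthetic participants

`generate_dataset()` is the data factory for every experiment.
Parameters are drawn from the generative priors (second moments are
standard deviations):

| model | prior |
|---|---|
| hyperbolic / hyperboloid | `log k ~ N(-5, 3)`, `log m ~ N(1, 5)` |
| hyperboloid | `s ~ N(0.8, 0.3)` truncated to `s > 0` (rejection) |
| direct difference | `u, v ~ N(0.8, 0.3)` truncated positive; `w ~ U(0, 1)` |

These are deliberately wide: they cover near-deterministic and
near-random responders and discounting rates from negligible to
extreme. Truncation by rejection (rather than clipping) keeps the
positive-parameter densities smooth, which the log-scale fits require.

Two design sources are provided. The fixed 27-item monetary choice
questionnaire (`mcq_design()`, SS today vs LL after 7–186 days) gives
the classic 27-bit response vector. Variable-length designs
(`generate_variable_design()`) draw, per trial,
`x_ss ~ U(5, 100)`, `x_ll = x_ss + Gamma(2, 15)`,
`t_ss ~ Gamma(1, 30)`, `t_ll = t_ss + Gamma(2, 30)` — gamma in
shape–scale parameterization, chosen so the payoff gap (mean 30
currency units) and delays (means 30/60 days) sit on the
questionnaire's natural scale — with the trial count uniform on the
integers 20–200. One master seed spawns a per-participant substream,
so any single participant can be regenerated in isolation.

The simulator emulates independent Bernoulli choices from a fixed
parameter vector. It does not emulate real-data features such as
lapses, fatigue, order effects, time-varying parameters, or model
heterogeneity within a participant — so passing recovery tests show
that inference inverts *this* generative family, not that real
behavior follows it.

## Simulation-inversion networks

Fixed-input networks take the 27-bit vector through tanh layers of
100, 66 and 33 units into either a linear regression head (one output
per parameter) or a 3-way softmax. Sequence networks encode each trial
as 5 channels — `x_ss, t_ss, x_ll, t_ll` scaled by 1/100, and the
choice coded ±1 — through an LSTM with 150 recurrent units
(sequence-to-last) and ReLU layers of 100, 80 and 30. The 1/100 input
scaling is ours: unscaled payoff/delay channels in the 0–400 range
destabilize recurrent training.

Regression targets are the transformed parameters — `log` for
`k, m, s, u, v` and `logit` for `w` — so back-transformed estimates
satisfy the constraints by construction. Training uses Adam with L2
penalty 1e-7; defaults are mini-batches of 1000 and up to 5000 epochs
for fixed-input networks, and mini-batches of 64 with global-norm
gradient clipping at 2 and 50 epochs for sequence networks. Loss is
mean squared error for estimators and categorical cross-entropy for
the classifier (three mutually exclusive labels). Early stopping is
available in principle but off: runs are fixed-length and fully
reproducible from `(config, seed)`. Weight initialization, batch
shuffling, crop windows and dropout masks all derive from the
training seed; training is single-threaded C++ (Armadillo), single
precision for the recurrent networks.

Recurrent training on long sequences needs two further choices that
fixed-input networks do not. First, the forget-gate bias initializes
at 3 (gate ≈ 0.95 open), so the sequence-final state can integrate
evidence from early trials from the first epoch on; with the common
init of 1 the initial memory half-life is a few trials and the
network spends many epochs stuck predicting the class base rate.
Second, a *crop curriculum*: for the first `crop_frac` (default 0.7)
of the epochs, each training sequence is replaced by a freshly drawn
random contiguous window of 20–`crop_len` (default 60) trials.
Because trials are independent and identically distributed within a
synthetic participant, a window is itself a valid shorter session
from the same generative model — the curriculum changes the length
mix of the training distribution, not its content. Short windows make
each optimization step three times cheaper and their gradients
propagate through far fewer timesteps; the remaining full-length
epochs then adapt the recurrent dynamics to test-time lengths. The
learning rate decays in two steps (×0.5, ×0.25) over the run.

Desk-scale experiment sizes (the package's own defaults, stated next
to each experiment): classifier training uses 20,000 simulations per
model with 150 epochs on the questionnaire, and 1,500–4,000 per model
with 90–100 epochs (85% cropped) for sequence networks; estimators use
12,000 per model with 250 epochs; held-out test sets are 400–2,000
participants per model. At these sizes the scored quantities
(held-out accuracies, correlations) have plateaued or nearly so;
full-scale settings are one configuration away.

## Dropout posteriors

Estimators built with `dropout = 0.5` knock out each unit of the last
hidden layer with probability 0.5 during training *and* at inference.
`sample_posterior()` applies the trained network repeatedly; each pass
instantiates one thinned network, and the spread of outputs
approximates a joint Bayesian posterior (the posterior of a deep
Gaussian process). Draws are independent — no chain, no burn-in, no
autocorrelation — and because the output layer is linear in the
dropped layer, the draw mean matches the no-dropout point estimate in
expectation. For group-level questions
(`sample_group_posterior()`), one thinned network is applied to all
participants per draw, and the across-participant mean of each draw is
one draw from the group-level posterior. Individual-level dropout
posteriors are approximately multivariate normal on the transformed
scale; sharply non-normal posteriors are outside what this
approximation can express.

## The MCMC benchmark

`fit_individual()` runs an adaptive random-walk Metropolis sampler on
the transformed scale with per-parameter proposals; proposal scales
adapt toward ~30% acceptance during burn-in (stochastic-approximation
updates every 50 iterations) and freeze afterwards, preserving
detailed balance in the sampling phase. Defaults are 4 chains of 4500
iterations with 1500 burn-in. Any correct posterior sampler satisfies
the same contracts; ours is validated against the conjugate
normal-normal closed form and against parameter recovery, not against
trace equality with any particular engine. Priors default to the
generative priors (so network estimates and MCMC posteriors answer the
same question); `transformed_normal_priors()` lets a fitted group
posterior serve as the prior of per-participant fits, the two-stage
protocol the model-recovery benchmark uses.

`fit_hierarchical()` places individual transformed parameters around
group locations with group scales; "uninformative" hyperpriors are
made concrete as `Normal(0, 10^2)` locations and `Uniform(0, 20)`
scales. Updates are Metropolis-within-Gibbs (conjugate draws for
locations, log-scale random walks for scales), batches are capped at
200 participants, and the split-Rhat gate is 1.05 — stricter than the
common 1.1, because chains are cheap at this model size. MAP estimates
are the stored draw with the highest joint log-density (sample argmax,
no separate optimizer); for symmetric posteriors this sits close to
the posterior mean, but it inherits single-draw noise, so dispersion
comparisons (e.g. shrinkage) should use posterior means.

## Model-comparison metrics

`AIC = 2p - 2 logL` and `BIC = p log(n) - 2 logL` with `n` the number
of trials the participant contributed (27 on the questionnaire; the
per-participant trial count is our convention, since alternatives such
as total observations across participants have no per-participant
meaning here). The maximized `logL` is read off the stored posterior
draws. DIC uses Spiegelhalter's form with the plug-in deviance at the
posterior mean of the transformed parameters; WAIC uses the
variance-based penalty, computed with the population variance so the
criterion is exactly invariant to duplicating draws. BIC converts to
posterior model probabilities through the Bayes-factor approximation
`BF = exp(-dBIC/2)` under equal (1/3) prior model probabilities.
Winners are the best criterion value, with exact ties broken by the
canonical model order (direct difference, hyperbolic, hyperboloid) —
deterministically, so reruns agree.

Calibration tables bin each decision's confidence to the nearest 10%
(11 levels; half-way values round away from zero) and tabulate
empirical accuracy per bin, pooling one decision — the
highest-probability model — per participant. Two summary notions of
"mean confidence" coexist and both are reported: the mean confidence
of the decisions (the reliability-curve quantity) and the mean
posterior probability assigned to the *true* generative model
(`mean_prob_true_*` in `run_model_recovery()`), which is the quantity
to compare against overall accuracy when asking whether an approach
is under- or overconfident about the truth.

## Known limitations

* **Identifiability ceilings.** Under the wide generative priors a
  sizable fraction of simulated participants behave deterministically
  (always SS or always LL) or at chance, so *no* estimator can
  recover their parameters. Measured with the MCMC posterior mean as
  the optimal reference, true-vs-estimate correlations top out near
  0.85 for `log k` and `w` on questionnaire data (and ~0.87 for
  `log k` even with 20–200-trial designs), even though network and
  MCMC estimates agree with each other at r ≈ 0.99. Recovery scores
  should be read against that ceiling, not against 1.
* `s`, `u` and `v` are poorly identified by immediate-vs-delayed
  money choices; expect low recovery correlations and strong
  posterior correlations among them. Freezing `v` (the restricted
  direct-difference variant, `fixed = c(v = 0.7)`) removes the
  dominant correlation axis.
* The classifier's accuracy ceiling is set by the generative overlap
  of the three model families; with the wide priors above, the
  Bayes-optimal assignment on 27-bit questionnaire data is itself
  about 73%, so held-out accuracies near 70% are near-optimal, and
  per-row confusion percentages of a well-converged classifier track
  the Bayes-optimal confusion rather than any particular published
  network's idiosyncrasies.
* Dropout posteriors inherit the Gaussian-process approximation; the
  hierarchical sampler assumes normal group distributions on the
  transformed scale.
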