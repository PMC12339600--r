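#' Canonical model labels
#'
#' The three intertemporal-choice models handled by the package, in the
#' canonical ordering used for classifier outputs, confusion matrices
#' and tie-breaking: direct difference, hyperbolic, hyperboloid.
#'
#' @return Character vector of length 3.
#' @export
model_labels <- function() {
  c("direct_difference", "hyperbolic", "hyperboloid")
}

.match_model <- function(model) {
  if (length(model) != 1L || !is.character(model))
    stop("`model` must be a single model label", call. = FALSE)
  match.arg(model, model_labels())
}

#' Number of free parameters per model
#'
#' @param model Model label (see [model_labels()]).
#' @return Integer parameter count (hyperbolic 2; hyperboloid and direct
#'   difference 3).
#' @export
n_params <- function(model) {
  switch(.match_model(model),
         hyperbolic = 2L, hyperboloid = 3L, direct_difference = 3L)
}

#' Parameter names on the natural and transformed scales
#'
#' Parameters are stored and fit on an unconstrained transformed scale:
#' log for the positive parameters (k, m, s, u, v) and logit for the
#' attention weight w, which lives in \[0, 1\].
#'
#' @param model Model label.
#' @param transformed If `TRUE`, return the transformed-scale names.
#' @return Character vector of parameter names.
#' @export
param_names <- function(model, transformed = FALSE) {
  nat <- switch(.match_model(model),
                hyperbolic = c("k", "m"),
                hyperboloid = c("k", "m", "s"),
                direct_difference = c("u", "v", "w"))
  if (!transformed) return(nat)
  ifelse(nat == "w", "logit_w", paste0("log_", nat))
}

#' Transform parameters to the unconstrained fitting scale
#'
#' @param model Model label.
#' @param params Named list/vector (single participant) or data frame
#'   (one row per participant) of natural-scale parameters.
#' @return Matrix (participants x parameters) on the transformed scale,
#'   with transformed-scale column names.
#' @export
transform_params <- function(model, params) {
  model <- .match_model(model)
  nat <- param_names(model)
  p <- if (is.data.frame(params)) params else as.data.frame(as.list(unlist(params)))
  if (!all(nat %in% names(p)))
    stop("missing parameter(s): ", paste(setdiff(nat, names(p)), collapse = ", "),
         call. = FALSE)
  out <- vapply(nat, function(nm) {
    x <- p[[nm]]
    if (nm == "w") {
      if (any(x < 0 | x > 1)) stop("w must lie in [0, 1]", call. = FALSE)
      qlogis(x)
    } else {
      if (any(x <= 0)) stop(nm, " must be > 0", call. = FALSE)
      log(x)
    }
  }, numeric(nrow(p)))
  out <- matrix(out, nrow = nrow(p),
                dimnames = list(NULL, param_names(model, transformed = TRUE)))
  out
}

#' Back-transform parameters to the natural scale
#'
#' @param model Model label.
#' @param z Numeric vector (one participant) or matrix (participants x
#'   parameters) on the transformed scale, in [param_names()] order.
#' @return Data frame of natural-scale parameters.
#' @export
untransform_params <- function(model, z) {
  model <- .match_model(model)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  nat <- param_names(model)
  stopifnot(ncol(z) == length(nat))
  out <- lapply(seq_along(nat), function(j) {
    if (nat[j] == "w") plogis(z[, j]) else exp(z[, j])
  })
  names(out) <- nat
  as.data.frame(out)
}

.check_params <- function(model, params) {
  nat <- param_names(model)
  p <- as.list(params)
  if (!all(nat %in% names(p)))
    stop("parameters for the ", model, " model must be named ",
         paste(nat, collapse = ", "), call. = FALSE)
  p <- p[nat]
  pos <- setdiff(nat, "w")
  for (nm in pos) if (any(!is.finite(p[[nm]]) | p[[nm]] <= 0))
    stop("parameter ", nm, " must be finite and > 0", call. = FALSE)
  if ("w" %in% nat && any(p$w < 0 | p$w > 1))
    stop("parameter w must lie in [0, 1]", call. = FALSE)
  p
}

#' Hyperbolic subjective value
#'
#' Discounted value of a payoff `x` delivered after delay `t`:
#' `v(x, t) = x / (1 + k t)`. The discounting rate `k` (1/days) controls
#' how quickly value decays with delay; larger `k` means steeper
#' discounting (more impulsive preferences).
#'
#' @param x Payoff (> 0, currency units).
#' @param t Delay in days (>= 0).
#' @param k Discounting rate (> 0).
#' @return Subjective value, same length as the longest argument.
#' @export
hyperbolic_value <- function(x, t, k) {
  if (any(x <= 0)) stop("payoff x must be > 0", call. = FALSE)
  if (any(t < 0)) stop("delay t must be >= 0", call. = FALSE)
  if (any(k <= 0)) stop("discounting rate k must be > 0", call. = FALSE)
  x / (1 + k * t)
}

#' Hyperboloid (modified Rachlin) subjective value
#'
#' Adds a time-sensitivity exponent `s` to hyperbolic discounting, with
#' delay entering as `(k t)^s` so that the units of `k` stay 1/days for
#' every `s`. Two forms are provided:
#'
#' * `payoff_scaled = TRUE` (default): `v = x / (1 + (k t)^s)`, which
#'   reduces exactly to [hyperbolic_value()] at `s = 1` and scales with
#'   the payoff.
#' * `payoff_scaled = FALSE`: `v = 1 / (1 + (k t)^s)`, the normalized
#'   form in which value lives on a 0-1 scale and payoffs do not enter.
#'   This is the form used by the package's canonical `"hyperboloid"`
#'   generative model (see [choice_prob()]), whose recovery and
#'   model-comparison behavior the bundled experiments characterize.
#'
#' @inheritParams hyperbolic_value
#' @param s Time-sensitivity exponent (> 0); `s < 1` compresses large
#'   delays, `s > 1` expands them.
#' @param payoff_scaled Which numerator to use (see Details).
#' @return Subjective value.
#' @export
hyperboloid_value <- function(x, t, k, s, payoff_scaled = TRUE) {
  if (any(x <= 0)) stop("payoff x must be > 0", call. = FALSE)
  if (any(t < 0)) stop("delay t must be >= 0", call. = FALSE)
  if (any(k <= 0)) stop("discounting rate k must be > 0", call. = FALSE)
  if (any(s <= 0)) stop("time sensitivity s must be > 0", call. = FALSE)
  num <- if (payoff_scaled) x else 1
  num / (1 + (k * t)^s)
}

#' Logistic choice rule
#'
#' Probability of choosing option 1 given the difference `d` in
#' subjective value between option 1 and option 2:
#' `Pr = 1 / (1 + exp(-d m))`. The slope `m` scales how
#' deterministically value differences translate into choices: as `m`
#' grows the rule approaches a step function, and as `m` approaches 0
#' choices approach coin flips.
#'
#' @param d Value difference (finite).
#' @param m Slope parameter (> 0).
#' @return Choice probability in (0, 1); 0 or 1 only in the
#'   floating-point overflow limit.
#' @export
logistic_choice_prob <- function(d, m) {
  if (any(m <= 0)) stop("slope m must be > 0", call. = FALSE)
  plogis(d * m)
}

.as_problems <- function(problems) {
  need <- c("x_ss", "t_ss", "x_ll", "t_ll")
  if (!is.data.frame(problems) || !all(need %in% names(problems)))
    stop("`problems` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  problems
}

#' Drift and noise of the direct-difference model
#'
#' The attribute-wise direct-difference model compares options dimension
#' by dimension. With option 1 the larger-later (LL) option and option 2
#' the smaller-sooner (SS) option, the mean evidence is
#' `d = w (x1^u - x2^u) - (1 - w) (t1^v - t2^v)` and its standard
#' deviation follows from the Bernoulli attention weight:
#' `sigma^2 = w a^2 + (1 - w) b^2 - d^2`, where `a = x1^u - x2^u` and
#' `b = t1^v - t2^v`. Algebraically `sigma^2 = w (1 - w) (a + b)^2`, so
#' the variance is always non-negative; tiny negative values from
#' floating-point rounding are clamped to zero.
#'
#' @param problems Data frame of choice problems with columns `x_ss`,
#'   `t_ss`, `x_ll`, `t_ll`.
#' @param params Named parameters `u`, `v` (> 0) and `w` in \[0, 1\].
#' @return List with numeric vectors `d` and `sigma` (one entry per
#'   problem).
#' @export
dd_drift_and_noise <- function(problems, params) {
  problems <- .as_problems(problems)
  p <- .check_params("direct_difference", params)
  a <- problems$x_ll^p$u - problems$x_ss^p$u
  b <- problems$t_ll^p$v - problems$t_ss^p$v
  d <- p$w * a - (1 - p$w) * b
  var <- p$w * a^2 + (1 - p$w) * b^2 - d^2
  list(d = d, sigma = sqrt(pmax(var, 0)))
}

#' Probability of choosing the larger-later option
#'
#' Per-trial choice probabilities under any of the three models. For the
#' hyperbolic and hyperboloid models the probability is the logistic
#' rule applied to the LL-minus-SS difference in subjective value; for
#' the direct-difference model it is `pnorm(d / sigma)`, the probability
#' that normally distributed evidence `N(d, sigma)` favors LL. When
#' `sigma = 0` (w at 0 or 1, or identical options) the rule degenerates
#' to a step function: 1 if `d > 0`, 0 if `d < 0`, 0.5 at `d = 0`. The
#' same step limit applies to the logistic models when `m` overflows.
#'
#' @param model Model label.
#' @param params Named natural-scale parameters for `model`.
#' @param problems Data frame of choice problems (`x_ss`, `t_ss`,
#'   `x_ll`, `t_ll`).
#' @param payoff_scaled Numerator convention for the hyperboloid model;
#'   the canonical generative model uses the normalized (unit) form.
#' @return Vector of probabilities of choosing larger-later, one per
#'   problem.
#' @export
choice_prob <- function(model, params, problems, payoff_scaled = FALSE) {
  model <- .match_model(model)
  problems <- .as_problems(problems)
  p <- .check_params(model, params)
  if (model == "direct_difference") {
    dn <- dd_drift_and_noise(problems, p)
    pr <- ifelse(dn$sigma > 0, pnorm(dn$d / pmax(dn$sigma, 1e-300)),
                 ifelse(dn$d > 0, 1, ifelse(dn$d < 0, 0, 0.5)))
    return(pr)
  }
  v_ll <- switch(model,
    hyperbolic = hyperbolic_value(problems$x_ll, problems$t_ll, p$k),
    hyperboloid = hyperboloid_value(problems$x_ll, problems$t_ll, p$k, p$s,
                                    payoff_scaled = payoff_scaled))
  v_ss <- switch(model,
    hyperbolic = hyperbolic_value(problems$x_ss, problems$t_ss, p$k),
    hyperboloid = hyperboloid_value(problems$x_ss, problems$t_ss, p$k, p$s,
                                    payoff_scaled = payoff_scaled))
  d <- v_ll - v_ss
  dm <- d * p$m
  pr <- plogis(dm)
  bad <- !is.finite(dm)  # 0 * Inf at exact indifference with huge m
  if (any(bad)) pr[bad] <- ifelse(d[bad] > 0, 1, ifelse(d[bad] < 0, 0, 0.5))
  pr
}

#' Bernoulli log-likelihood of a response vector
#'
#' Sum of per-trial Bernoulli log-likelihoods with probabilities from
#' [choice_prob()]. Probabilities are clamped to
#' \[1e-12, 1 - 1e-12\] before taking logs so that deterministic
#' predictions cannot produce `-Inf` from a single surprising choice.
#'
#' @inheritParams choice_prob
#' @param responses Binary vector, one entry per problem; 1 means the
#'   larger-later option was chosen.
#' @return Scalar log-likelihood (always <= 0).
#' @export
log_likelihood <- function(model, params, problems, responses,
                           payoff_scaled = FALSE) {
  problems <- .as_problems(problems)
  if (length(responses) != nrow(problems))
    stop("length(responses) must equal the number of problems", call. = FALSE)
  if (!all(responses %in% c(0, 1)))
    stop("responses must be binary (0 = smaller-sooner, 1 = larger-later)",
         call. = FALSE)
  p <- choice_prob(model, params, problems, payoff_scaled = payoff_scaled)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(ifelse(responses == 1, log(p), log1p(-p)))
}
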