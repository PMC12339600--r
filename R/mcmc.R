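#' MCMC sampler configuration
#'
#' Defaults follow the reference protocol: four chains of 4500 samples
#' with 1500 burn-in draws each, no thinning. The sampler is an
#' adaptive random-walk Metropolis on the transformed (unconstrained)
#' parameter scale with per-parameter proposals; proposal scales adapt
#' toward a ~30% acceptance rate during burn-in and are frozen
#' afterwards.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Total iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 4500L, n_burn = 1500L,
                        thin = 1L, seed = 1L) {
  stopifnot(n_burn < n_iter, n_chains >= 1, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Hierarchy specification for multilevel fits
#'
#' Individual transformed parameters are modeled as normal around
#' group-level locations with group-level scales. Hyperpriors are
#' deliberately weak: locations `Normal(0, 10^2)` and scales
#' `Uniform(0, 20)` on the transformed scale.
#'
#' @param loc_sd SD of the normal hyperprior on group locations.
#' @param scale_upper Upper bound of the uniform hyperprior on group
#'   scales.
#' @param batch_size Largest participant batch fit at once.
#' @return Object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(loc_sd = 10, scale_upper = 20,
                           batch_size = 200L) {
  stopifnot(loc_sd > 0, scale_upper > 0, batch_size >= 2)
  structure(list(loc_sd = loc_sd, scale_upper = scale_upper,
                 batch_size = as.integer(batch_size)),
            class = "hierarchy_spec")
}

.model_id <- function(model) {
  switch(model, direct_difference = 0L, hyperbolic = 1L, hyperboloid = 2L)
}

.design_matrix <- function(design) {
  design <- .as_problems(design)
  cbind(design$x_ss, design$t_ss, design$x_ll, design$t_ll)
}

# Prior matrix for the C++ sampler: one {type, a, b} row per
# transformed parameter. Accepts a prior_spec() list (generative
# priors) or a transformed_normal_priors() object (e.g. fitted
# group-level priors).
.prior_matrix <- function(model, priors) {
  tnames <- param_names(model, transformed = TRUE)
  if (inherits(priors, "transformed_priors")) {
    stopifnot(all(tnames %in% names(priors$mean)))
    return(cbind(0, priors$mean[tnames], priors$sd[tnames]))
  }
  nat <- param_names(model)
  stopifnot(all(nat %in% names(priors)))
  t(vapply(nat, function(nm) {
    s <- priors[[nm]]
    switch(s$dist,
           lognormal = c(0, s$mean, s$sd),
           truncnormal = c(1, s$mean, s$sd),
           uniform = c(2, 0, 0))
  }, numeric(3)))
}

#' Normal priors on the transformed parameter scale
#'
#' Used to hand fitted group-level distributions to
#' [fit_individual()], e.g. for the two-stage protocol in which each
#' candidate model is first fit hierarchically and its group posterior
#' then serves as the prior of per-participant fits.
#'
#' @param mean,sd Named vectors over transformed parameter names
#'   (`log_k`, `log_m`, ...).
#' @return Object of class `transformed_priors`.
#' @export
transformed_normal_priors <- function(mean, sd) {
  stopifnot(identical(names(mean), names(sd)), all(sd > 0))
  structure(list(mean = mean, sd = sd), class = "transformed_priors")
}

#' Fit one participant by adaptive Metropolis MCMC
#'
#' Samples the posterior proportional to the Bernoulli likelihood of
#' the observed choices times the prior. By default the prior matches
#' the generative prior of [sample_prior()], mirroring the match built
#' into the simulation-inversion networks.
#'
#' @param model Model label.
#' @param design Design data frame.
#' @param responses Binary response vector.
#' @param priors A [prior_spec()] list or [transformed_normal_priors()].
#' @param config An [mcmc_config()].
#' @param keep_pointwise Keep the draws x trials pointwise
#'   log-likelihood matrix (needed for WAIC).
#' @param hyperboloid_form Which hyperboloid value function the
#'   likelihood uses: `"normalized"` (the canonical generative form,
#'   `1/(1+(kt)^s)`) or `"payoff_scaled"` (`x/(1+(kt)^s)`, which nests
#'   the hyperbolic model at `s = 1` and is the form the likelihood
#'   benchmark fits).
#' @return Object of class `itc_fit`: `samples` (a
#'   [posterior_samples()] with chain provenance and joint log-density
#'   per draw), `loglik` per draw, `map` and `posterior_mean`
#'   (transformed scale), `rhat` per parameter, acceptance rates, and
#'   optionally `pointwise`.
#' @export
fit_individual <- function(model, design, responses,
                           priors = prior_spec(model),
                           config = mcmc_config(),
                           keep_pointwise = FALSE,
                           hyperboloid_form = c("normalized",
                                                "payoff_scaled")) {
  model <- .match_model(model)
  hyperboloid_form <- match.arg(hyperboloid_form)
  D <- .design_matrix(design)
  if (length(responses) != nrow(D))
    stop("responses and design are misaligned", call. = FALSE)
  pm <- .prior_matrix(model, priors)
  mid <- .model_id(model)
  if (model == "hyperboloid" && hyperboloid_form == "payoff_scaled")
    mid <- 4L
  res <- rwm_fit_cpp(mid, D, as.integer(responses), pm,
                     config$n_chains, config$n_iter, config$n_burn,
                     config$thin, config$seed, keep_pointwise)
  tnames <- param_names(model, transformed = TRUE)
  colnames(res$draws) <- tnames
  samples <- posterior_samples(res$draws, source = "mcmc",
                               chain = res$chain, logpost = res$logpost)
  best <- which.max(res$logpost)
  per_chain <- split.data.frame(as.data.frame(res$draws), res$chain)
  rhat <- convergence_check(lapply(per_chain, as.matrix))
  out <- list(model = model, model_id = mid, samples = samples,
              loglik = res$loglik,
              map = setNames(res$draws[best, ], tnames),
              posterior_mean = setNames(colMeans(res$draws), tnames),
              rhat = rhat, accept_rate = res$accept_rate,
              n_trials = nrow(D), config = config)
  if (keep_pointwise) out$pointwise <- res$pointwise
  structure(out, class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("<itc_fit> %s, %d draws, %d trials\n", x$model,
              x$samples$n_draws, x$n_trials))
  print(round(rbind(map = x$map, mean = x$posterior_mean,
                    rhat = x$rhat), 3))
  invisible(x)
}

#' Hierarchical (multilevel) Bayesian fit of a participant batch
#'
#' Individual transformed parameters are drawn from group-level normal
#' distributions whose location and scale get weak hyperpriors (see
#' [hierarchy_spec()]); sampling is Metropolis-within-Gibbs. Sharing
#' the group-level distribution shrinks poorly constrained individual
#' estimates toward the group's central tendency.
#'
#' @param model Model label.
#' @param dataset An `itc_dataset` (all participants are fit), or a
#'   list with elements `designs` (one design, or one per participant)
#'   and `responses` (list of vectors).
#' @param hierarchy A [hierarchy_spec()].
#' @param config An [mcmc_config()].
#' @param keep_individual Keep full per-draw trajectories for the
#'   first `keep_individual` participants.
#' @param hyperboloid_form As in [fit_individual()].
#' @return Object of class `itc_hier_fit`: `group` samples (locations
#'   `mu_*` then scales `sigma_*`), per-participant posterior means and
#'   joint-MAP estimates (transformed scale), per-parameter group
#'   `rhat`, and the fitted group posterior summarized as
#'   [transformed_normal_priors()] in `$group_priors`.
#' @export
fit_hierarchical <- function(model, dataset,
                             hierarchy = hierarchy_spec(),
                             config = mcmc_config(),
                             keep_individual = 0L,
                             hyperboloid_form = c("normalized",
                                                  "payoff_scaled")) {
  model <- .match_model(model)
  hyperboloid_form <- match.arg(hyperboloid_form)
  if (inherits(dataset, "itc_dataset")) {
    if (dataset$design_kind == "mcq_fixed") {
      designs <- list(.design_matrix(dataset$designs))
      resps <- lapply(seq_len(nrow(dataset$responses)),
                      function(i) as.integer(dataset$responses[i, ]))
    } else {
      designs <- lapply(dataset$designs, .design_matrix)
      resps <- lapply(dataset$responses, as.integer)
    }
  } else {
    designs <- dataset$designs
    if (is.data.frame(designs)) designs <- list(designs)
    designs <- lapply(designs, .design_matrix)
    resps <- lapply(dataset$responses, as.integer)
  }
  n <- length(resps)
  if (n < 2) stop("hierarchy undefined for a batch of 1", call. = FALSE)
  if (n > hierarchy$batch_size)
    stop("batch of ", n, " exceeds configured batch size ",
         hierarchy$batch_size, call. = FALSE)
  P <- n_params(model)
  mid <- .model_id(model)
  if (model == "hyperboloid" && hyperboloid_form == "payoff_scaled")
    mid <- 4L
  res <- hier_fit_cpp(mid, designs, resps, P,
                      config$n_chains, config$n_iter, config$n_burn,
                      config$thin, config$seed, hierarchy$loc_sd,
                      hierarchy$scale_upper, as.integer(keep_individual))
  tnames <- param_names(model, transformed = TRUE)
  gnames <- c(paste0("mu_", tnames), paste0("sigma_", tnames))
  colnames(res$group) <- gnames
  per_chain <- split.data.frame(as.data.frame(res$group), res$chain)
  rhat <- convergence_check(lapply(per_chain, as.matrix))
  colnames(res$individual_mean) <- tnames
  colnames(res$individual_map) <- tnames
  mu_hat <- colMeans(res$group[, seq_len(P), drop = FALSE])
  sd_hat <- colMeans(res$group[, P + seq_len(P), drop = FALSE])
  structure(list(
    model = model,
    group = posterior_samples(res$group, source = "mcmc",
                              chain = res$chain,
                              logpost = res$joint_logpost),
    individual_mean = res$individual_mean,
    individual_map = res$individual_map,
    individual_draws = res$individual_draws,
    rhat = rhat,
    group_priors = transformed_normal_priors(
      setNames(as.numeric(mu_hat), tnames),
      setNames(as.numeric(sd_hat), tnames)),
    hierarchy = hierarchy, config = config),
    class = "itc_hier_fit")
}

#' @export
print.itc_hier_fit <- function(x, ...) {
  cat(sprintf("<itc_hier_fit> %s, %d participants, %d group draws\n",
              x$model, nrow(x$individual_mean), x$group$n_draws))
  print(round(rbind(mean = colMeans(x$group$draws), rhat = x$rhat), 3))
  invisible(x)
}

#' Maximum a posteriori estimate from stored draws
#'
#' Returns the stored draw with the highest joint log-density (the
#' sample argmax, not a separate optimization); for the symmetric
#' posteriors typical of these models this is very close to the
#' posterior mean.
#'
#' @param samples A [posterior_samples()] object (with `logpost`), or
#'   a draws matrix.
#' @param log_density Joint log-density function of one draw; required
#'   when `samples` carries no stored densities.
#' @return Named parameter vector (transformed scale).
#' @export
map_estimate <- function(samples, log_density = NULL) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws
           else as.matrix(samples)
  if (nrow(draws) == 0) stop("no draws", call. = FALSE)
  lp <- if (inherits(samples, "posterior_samples") &&
            !is.null(samples$logpost)) samples$logpost
        else if (!is.null(log_density)) apply(draws, 1, log_density)
        else stop("need stored log-densities or a `log_density` function",
                  call. = FALSE)
  draws[which.max(lp), ]
}

#' Split-chain potential-scale-reduction diagnostic
#'
#' Computes the split-\eqn{\widehat{R}} statistic per parameter: each
#' chain is split in half and the usual between/within variance ratio
#' is applied to the resulting half-chains. Values near 1 indicate the
#' chains agree; the package flags parameters above 1.05.
#'
#' @param chains List of draws matrices (one per chain, equal
#'   dimensions), or a single matrix with a `chain` attribute.
#' @return Named vector of diagnostics, with attribute `"flagged"`
#'   naming parameters above 1.05.
#' @export
convergence_check <- function(chains) {
  if (is.matrix(chains)) chains <- list(chains)
  stopifnot(is.list(chains), length(chains) >= 1)
  lens <- vapply(chains, nrow, integer(1))
  if (length(unique(lens)) != 1)
    stop("chains must have equal length", call. = FALSE)
  if (length(chains) < 2 && lens[1] < 4)
    stop("need at least 2 chains (or one splittable chain)", call. = FALSE)
  halves <- list()
  for (ch in chains) {
    h <- floor(nrow(ch) / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[h + seq_len(h), , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  P <- ncol(halves[[1]])
  rhat <- numeric(P)
  for (j in seq_len(P)) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- n * var(means)
    vhat <- (n - 1) / n * W + B / n
    rhat[j] <- if (W > 0) sqrt(vhat / W) else 1
  }
  names(rhat) <- colnames(chains[[1]])
  attr(rhat, "flagged") <- names(rhat)[rhat > 1.05]
  rhat
}

#' Export posterior draws as a delimited-text table
#'
#' @param samples A [posterior_samples()] object.
#' @param path Output file.
#' @param participant_id Identifier written with every row.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(samples, path, participant_id = 1L) {
  stopifnot(inherits(samples, "posterior_samples"))
  d <- data.frame(participant_id = participant_id,
                  draw = seq_len(samples$n_draws),
                  chain = if (is.null(samples$chain)) 1L else samples$chain)
  d <- cbind(d, as.data.frame(samples$draws))
  .write_atomic(d, path)
}

# Gaussian conjugate toy target (y ~ N(theta, 1), theta ~ N(m0, s0)):
# used to validate the Metropolis kernel against the closed-form
# posterior.
.fit_gaussian_toy <- function(y, prior_mean, prior_sd,
                              config = mcmc_config()) {
  D <- cbind(y, 0, 0, 0)
  pm <- matrix(c(0, prior_mean, prior_sd), 1)
  res <- rwm_fit_cpp(3L, D, rep(1L, length(y)), pm, config$n_chains,
                     config$n_iter, config$n_burn, config$thin,
                     config$seed, FALSE)
  colnames(res$draws) <- "theta"
  posterior_samples(res$draws, source = "mcmc", chain = res$chain,
                    logpost = res$logpost)
}
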