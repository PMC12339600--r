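test_that("sampler reproduces the conjugate-normal closed form", {
  set.seed(31)
  y <- rnorm(8, 1.3, 1)
  n <- length(y)
  m0 <- -0.5; s0 <- 2
  post_prec <- n + 1 / s0^2
  post_mean <- (sum(y) + m0 / s0^2) / post_prec
  post_sd <- sqrt(1 / post_prec)
  toy <- itcnet:::.fit_gaussian_toy(y, m0, s0,
    mcmc_config(n_chains = 4, n_iter = 4500, n_burn = 1500, seed = 32))
  n_eff_guess <- 400  # conservative for an adaptive RW chain
  expect_lt(abs(mean(toy$draws) - post_mean),
            3 * post_sd / sqrt(n_eff_guess))
  expect_lt(abs(sd(toy$draws) - post_sd), 3 * post_sd / sqrt(n_eff_guess))
})

test_that("individual fits recover generating parameters and are seeded", {
  des <- generate_variable_design(33, n_trials = 200)
  resp <- simulate_participant("hyperbolic", list(k = exp(-3), m = exp(2)),
                               des, seed = 34)
  cfg <- mcmc_config(n_chains = 2, n_iter = 2500, n_burn = 1000, seed = 35)
  fit <- fit_individual("hyperbolic", des, resp, config = cfg)
  expect_lt(abs(fit$posterior_mean[["log_k"]] + 3), 0.5)
  expect_true(all(fit$rhat < 1.05))
  expect_true(all(fit$accept_rate > 0.1 & fit$accept_rate < 0.6))
  fit2 <- fit_individual("hyperbolic", des, resp, config = cfg)
  expect_identical(fit$samples$draws, fit2$samples$draws)
  # all-larger-later data pushes the discounting rate below its prior mean
  flat <- fit_individual("hyperbolic", mcq_design(), rep(1L, 27),
                         config = cfg)
  expect_lt(flat$posterior_mean[["log_k"]], -5)
})

test_that("MAP extraction is the stored-draw argmax", {
  set.seed(36)
  draws <- matrix(rnorm(20000), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  lp <- -rowSums(draws^2) / 2
  ps <- posterior_samples(draws, source = "mcmc", logpost = lp)
  map <- map_estimate(ps)
  expect_equal(map, draws[which.max(lp), ])
  # unimodal symmetric: MAP close to the mean (within 0.1 posterior SD)
  expect_lt(max(abs(map - colMeans(draws))), 0.1 * max(apply(draws, 2, sd)))
  # single draw returns that draw; duplicating the argmax changes nothing
  one <- posterior_samples(draws[1, , drop = FALSE], source = "mcmc",
                           logpost = lp[1])
  expect_equal(map_estimate(one), draws[1, ])
  dup <- posterior_samples(rbind(draws, draws[which.max(lp), ]),
                           source = "mcmc", logpost = c(lp, max(lp)))
  expect_equal(map_estimate(dup), map)
  # a log-density function works when no densities are stored
  expect_equal(map_estimate(draws, function(z) -sum(z^2) / 2), map)
})

test_that("split-Rhat flags separated chains and passes identical ones", {
  set.seed(37)
  null_chains <- list(matrix(rnorm(1e4), ncol = 1),
                      matrix(rnorm(1e4), ncol = 1))
  r_null <- convergence_check(null_chains)
  expect_lt(r_null[1], 1.01)
  apart <- list(matrix(rnorm(2000, -5), ncol = 1),
                matrix(rnorm(2000, 5), ncol = 1))
  expect_gt(convergence_check(apart)[1], 1.1)
  same <- matrix(rnorm(1000), ncol = 1)
  expect_lt(convergence_check(list(same, same))[1], 1.01)
  expect_error(convergence_check(list(matrix(rnorm(10), ncol = 1),
                                      matrix(rnorm(20), ncol = 1))),
               "equal length")
})

test_that("hierarchical fits shrink and recover the group location", {
  ds <- generate_dataset("hyperbolic", 60, design = "mcq",
                         split = c(train = 0, validation = 0, test = 1),
                         seed = 38)
  cfg <- mcmc_config(n_chains = 2, n_iter = 2200, n_burn = 1000, seed = 39)
  hf <- fit_hierarchical("hyperbolic", ds, config = cfg)
  expect_lt(abs(mean(hf$group$draws[, "mu_log_k"]) + 5), 1.2)
  expect_true(all(hf$rhat[1:2] < 1.1))  # location parameters
  # shrinkage: sharing a group-level distribution pulls individual
  # estimates together relative to independent weakly informed fits
  # (compared on posterior means; single-draw MAPs carry draw noise)
  icfg <- mcmc_config(n_chains = 2, n_iter = 1500, n_burn = 600, seed = 40)
  weak <- transformed_normal_priors(c(log_k = 0, log_m = 0),
                                    c(log_k = 10, log_m = 10))
  solo <- vapply(seq_len(60), function(i)
    fit_individual("hyperbolic", mcq_design(), ds$responses[i, ],
                   priors = weak,
                   config = icfg)$posterior_mean[["log_k"]], numeric(1))
  expect_lt(var(hf$individual_mean[, "log_k"]), var(solo))
  expect_error(
    fit_hierarchical("hyperbolic",
                     list(designs = mcq_design(),
                          responses = list(rep(1L, 27)))),
    "batch of 1")
})

test_that("hierarchical and individual estimates agree given many trials", {
  # restricted to the identifiable regime (moderate discounting, choice
  # behavior neither deterministic nor random); outside it the two
  # priors dominate and the estimates legitimately diverge
  set.seed(41)
  n <- 16
  pars <- data.frame(k = exp(runif(n, -5, 0)), m = exp(runif(n, 0.5, 2.5)))
  designs <- lapply(seq_len(n), function(i)
    generate_variable_design(n_trials = 180))
  resps <- lapply(seq_len(n), function(i)
    simulate_participant("hyperbolic", as.list(pars[i, ]), designs[[i]]))
  cfg <- mcmc_config(n_chains = 2, n_iter = 2000, n_burn = 900, seed = 43)
  hf <- fit_hierarchical("hyperbolic",
                         list(designs = designs, responses = resps),
                         config = cfg)
  solo <- vapply(seq_len(n), function(i)
    fit_individual("hyperbolic", designs[[i]], resps[[i]],
                   config = cfg)$posterior_mean[["log_k"]], numeric(1))
  expect_gt(cor(hf$individual_mean[, "log_k"], solo), 0.95)
})
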