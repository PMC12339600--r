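test_that("hyperbolic value matches direct evaluation and limits", {
  expect_equal(hyperbolic_value(10, 0, 0.5), 10)
  expect_equal(hyperbolic_value(20, 5, 0.1), 40 / 3)
  expect_equal(hyperbolic_value(100, 30, 1), 100 / 31)
  # strictly decreasing in delay and in rate
  t <- seq(0, 100, 5)
  expect_true(all(diff(hyperbolic_value(10, t, 0.2)) < 0))
  k <- seq(0.01, 2, 0.05)
  expect_true(all(diff(hyperbolic_value(10, 10, k)) < 0))
  expect_error(hyperbolic_value(-1, 0, 0.5), "payoff")
  expect_error(hyperbolic_value(10, 0, 0), "rate")
})

test_that("hyperboloid value reduces to hyperbolic at s = 1", {
  expect_equal(hyperboloid_value(20, 5, 0.1, 1),
               hyperbolic_value(20, 5, 0.1))
  expect_equal(hyperboloid_value(10, 0, 0.3, 0.5), 10)
  expect_equal(hyperboloid_value(50, 100, 0.1, 0.5),
               50 / (1 + sqrt(10)))
  set.seed(1)
  for (i in 1:200) {
    x <- runif(1, 1, 100); t <- runif(1, 0, 200); k <- exp(runif(1, -8, 2))
    expect_identical(hyperboloid_value(x, t, k, 1),
                     hyperbolic_value(x, t, k))
  }
  # normalized form ignores the payoff and lives in (0, 1]
  expect_equal(hyperboloid_value(50, 0, 0.1, 0.5, payoff_scaled = FALSE), 1)
  expect_equal(hyperboloid_value(50, 100, 0.1, 0.5, payoff_scaled = FALSE),
               hyperboloid_value(99, 100, 0.1, 0.5, payoff_scaled = FALSE))
})

test_that("logistic choice rule is symmetric and overflow-safe", {
  expect_equal(logistic_choice_prob(0, 3), 0.5)
  expect_equal(logistic_choice_prob(2, 1), 1 / (1 + exp(-2)))
  expect_equal(logistic_choice_prob(-2, 1),
               1 - logistic_choice_prob(2, 1))
  expect_equal(logistic_choice_prob(1e6, 1e6), 1)
  expect_equal(logistic_choice_prob(-1e6, 1e6), 0)
  set.seed(2)
  d <- rnorm(100, 0, 5)
  expect_equal(logistic_choice_prob(d, 2) + logistic_choice_prob(-d, 2),
               rep(1, 100))
})

test_that("direct-difference drift and noise match the closed form", {
  dn <- dd_drift_and_noise(
    data.frame(x_ss = 10, t_ss = 0, x_ll = 20, t_ll = 30),
    list(u = 1, v = 1, w = 0.5))
  expect_equal(dn$d, -10)
  expect_equal(dn$sigma, 20)
  # w at the boundary: no attribute variability left
  dn1 <- dd_drift_and_noise(toy_problems(), list(u = 1, v = 1, w = 1))
  expect_equal(dn1$sigma, rep(0, 3))
  # identical options: zero drift and zero noise
  dn0 <- dd_drift_and_noise(
    data.frame(x_ss = 15, t_ss = 10, x_ll = 15, t_ll = 10),
    list(u = 0.8, v = 0.9, w = 0.4))
  expect_equal(dn0$d, 0)
  expect_equal(dn0$sigma, 0)
})

test_that("sigma^2 equals w(1-w)(a+b)^2 across random draws", {
  set.seed(3)
  for (i in 1:10000) {
    pr <- data.frame(x_ss = runif(1, 1, 100), t_ss = runif(1, 0, 100),
                     x_ll = runif(1, 1, 400), t_ll = runif(1, 0, 400))
    u <- runif(1, 0.1, 2); v <- runif(1, 0.1, 2); w <- runif(1)
    dn <- dd_drift_and_noise(pr, list(u = u, v = v, w = w))
    a <- pr$x_ll^u - pr$x_ss^u
    b <- pr$t_ll^v - pr$t_ss^v
    # identity up to round-off, which scales with the subtracted terms
    scale <- w * a^2 + (1 - w) * b^2 + 1
    expect_lt(abs(dn$sigma^2 - w * (1 - w) * (a + b)^2), 1e-10 * scale)
  }
})

test_that("choice probabilities respect limits and degenerate cases", {
  mcq <- mcq_design()
  # no discounting: larger-later always preferred
  p <- choice_prob("hyperbolic", list(k = 1e-12, m = 1e6), mcq)
  expect_true(all(p > 0.999))
  # direct difference with sigma = 0 degenerates to a step function
  p0 <- choice_prob("direct_difference", list(u = 1, v = 1, w = 1), mcq)
  expect_true(all(p0 == 1))  # w = 1: only payoffs matter, x_ll > x_ss
  p5 <- choice_prob("direct_difference", list(u = 1, v = 1, w = 0.5),
                    data.frame(x_ss = 10, t_ss = 0, x_ll = 20, t_ll = 30))
  expect_equal(p5, pnorm(-0.5), tolerance = 1e-12)
  # indifference at identical options
  same <- data.frame(x_ss = 20, t_ss = 10, x_ll = 20, t_ll = 10)
  for (mo in model_labels()) {
    pars <- as.list(random_params(mo))
    expect_equal(choice_prob(mo, pars, same), 0.5)
  }
  expect_error(choice_prob("weibull", list(k = 1), mcq))
})

test_that("larger-later preference is monotone in k and in w", {
  mcq <- mcq_design()
  set.seed(4)
  for (i in 1:50) {
    m <- exp(runif(1, -2, 3))
    k1 <- exp(runif(1, -7, 0)); k2 <- k1 * runif(1, 1.5, 10)
    p1 <- choice_prob("hyperbolic", list(k = k1, m = m), mcq)
    p2 <- choice_prob("hyperbolic", list(k = k2, m = m), mcq)
    expect_true(all(p2 <= p1 + 1e-12))
    s <- runif(1, 0.3, 1.5)
    q1 <- choice_prob("hyperboloid", list(k = k1, m = m, s = s), mcq)
    q2 <- choice_prob("hyperboloid", list(k = k2, m = m, s = s), mcq)
    expect_true(all(q2 <= q1 + 1e-12))
    u <- runif(1, 0.3, 1.5); v <- runif(1, 0.3, 1.5)
    w1 <- runif(1, 0.05, 0.95); w2 <- w1 * runif(1, 0.2, 0.9)
    r1 <- choice_prob("direct_difference", list(u = u, v = v, w = w1), mcq)
    r2 <- choice_prob("direct_difference", list(u = u, v = v, w = w2), mcq)
    expect_true(all(r2 <= r1 + 1e-12))
  }
})

test_that("log-likelihood sums Bernoulli terms with clamping", {
  same <- data.frame(x_ss = rep(20, 27), t_ss = rep(10, 27),
                     x_ll = rep(20, 27), t_ll = rep(10, 27))
  ll <- log_likelihood("hyperbolic", list(k = 0.1, m = 1), same,
                       rep(1, 27))
  expect_equal(ll, 27 * log(0.5))
  # single trial at p = 0.8: pick parameters that give exactly that
  pr <- data.frame(x_ss = 10, t_ss = 0, x_ll = 20, t_ll = 30)
  d <- hyperbolic_value(20, 30, 0.01) - 10
  ll1 <- log_likelihood("hyperbolic", list(k = 0.01, m = log(4) / d), pr, 1)
  expect_equal(ll1, log(0.8), tolerance = 1e-12)
  # order invariance
  mcq <- mcq_design()
  set.seed(5)
  resp <- rbinom(27, 1, 0.5)
  ord <- sample(27)
  expect_equal(
    log_likelihood("hyperboloid", list(k = 0.02, m = 2, s = 0.8),
                   mcq, resp),
    log_likelihood("hyperboloid", list(k = 0.02, m = 2, s = 0.8),
                   mcq[ord, ], resp[ord]))
  # clamping keeps the likelihood finite under deterministic predictions
  llc <- log_likelihood("hyperbolic", list(k = 1e-12, m = 1e9), mcq,
                        rep(0, 27))
  expect_true(is.finite(llc))
  expect_equal(llc, 27 * log(1e-12), tolerance = 1e-6)
  expect_error(log_likelihood("hyperbolic", list(k = 1, m = 1), mcq,
                              rep(1, 26)), "length")
  expect_error(log_likelihood("hyperbolic", list(k = 1, m = 1), mcq,
                              c(rep(1, 26), 2)), "binary")
})

test_that("probabilities stay in [0,1] and log-likelihood is never positive", {
  mcq <- mcq_design()
  set.seed(6)
  for (mo in model_labels()) {
    for (i in 1:30) {
      pars <- as.list(random_params(mo))
      p <- choice_prob(mo, pars, mcq)
      expect_true(all(p >= 0 & p <= 1))
      resp <- rbinom(27, 1, p)
      expect_lte(log_likelihood(mo, pars, mcq, resp), 0)
    }
  }
})

test_that("parameter transforms round-trip and enforce constraints", {
  for (mo in model_labels()) {
    pars <- random_params(mo, 20)
    z <- transform_params(mo, pars)
    expect_identical(colnames(z), param_names(mo, transformed = TRUE))
    back <- untransform_params(mo, z)
    expect_equal(as.data.frame(pars), back, tolerance = 1e-12)
  }
  expect_error(transform_params("hyperbolic", list(k = -1, m = 1)))
  expect_error(transform_params("direct_difference",
                                list(u = 1, v = 1, w = 1.2)))
})
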