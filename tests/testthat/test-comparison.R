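test_that("information criteria follow their formulas", {
  ic <- information_criteria(-10, 2, 27)
  expect_equal(ic[["AIC"]], 24)
  expect_equal(ic[["BIC"]], 20 + 2 * log(27))
  # penalty monotonicity at equal likelihood
  ic3 <- information_criteria(-10, 3, 27)
  expect_true(ic3[["AIC"]] > ic[["AIC"]] && ic3[["BIC"]] > ic[["BIC"]])
  expect_equal(information_criteria(-10, 2, 1)[["BIC"]], 20)
})

test_that("DIC matches its definition and penalizes posterior width", {
  dev_fn <- function(z) c("1" = 10, "3" = 12, "2" = 9)[[as.character(z[1])]]
  out <- compute_dic(matrix(c(1, 3), ncol = 1), dev_fn)
  expect_equal(out$mean_deviance, 11)
  expect_equal(out$p_D, 2)
  expect_equal(out$DIC, 13)
  # point-mass posterior: no effective parameters
  pm <- compute_dic(matrix(rep(2, 50), ncol = 1), function(z) 7)
  expect_equal(pm$p_D, 0)
  expect_equal(pm$DIC, 7)
  # quadratic deviance: widening the posterior (same mean) raises p_D
  set.seed(21)
  quad <- function(z) sum(z^2)
  narrow <- matrix(rnorm(4000, 0, 0.5), ncol = 2)
  wide <- matrix(rnorm(4000, 0, 1.5), ncol = 2)
  expect_gt(compute_dic(wide, quad)$p_D, compute_dic(narrow, quad)$p_D)
  expect_error(compute_dic(matrix(numeric(0), 0, 1), quad), "draws")
})

test_that("WAIC matches a brute-force implementation of the formulas", {
  pw <- matrix(log(0.5), 2, 1)
  out <- compute_waic(pw)
  expect_equal(out$lppd, log(0.5))
  expect_equal(out$p_waic, 0)
  expect_equal(out$WAIC, -2 * log(0.5), tolerance = 1e-12)
  # duplicating draws changes nothing
  set.seed(22)
  m <- matrix(rnorm(60, -1, 0.4), 10, 6)
  expect_equal(compute_waic(m)$WAIC, compute_waic(rbind(m, m))$WAIC)
  # independent oracle: direct transcription of the definitions
  brute <- function(mat) {
    lppd <- sum(log(apply(exp(mat), 2, mean)))
    p <- sum(apply(mat, 2, function(x) sum((x - mean(x))^2) / length(x)))
    -2 * (lppd - p)
  }
  expect_equal(compute_waic(m)$WAIC, brute(m), tolerance = 1e-10)
  expect_warning(compute_waic(matrix(log(0.5), 1, 3)), "single draw")
})

test_that("BIC posterior probabilities follow the Bayes-factor identity", {
  expect_equal(bic_posterior_probs(c(5, 5, 5)), rep(1 / 3, 3))
  w <- c(1, exp(-1), exp(-2))
  expect_equal(bic_posterior_probs(c(0, 2, 4)), w / sum(w))
  expect_equal(bic_posterior_probs(c(0, 2, 4)),
               c(0.6652, 0.2447, 0.0900), tolerance = 1e-3)
  # shift invariance
  b <- c(130.2, 128.9, 135.4)
  expect_equal(bic_posterior_probs(b), bic_posterior_probs(b - 100))
  # two-model reduction reproduces BF = exp(-dBIC/2)
  p2 <- bic_posterior_probs(c(10, 13))
  expect_equal(p2[1] / p2[2], exp(1.5), tolerance = 1e-12)
})

test_that("confusion matrices are row-normalized with correct accuracy", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"),
                         labels = c("A", "B"))
  expect_equal(cm$percent["A", ], c(A = 50, B = 50))
  expect_equal(cm$percent["B", ], c(A = 0, B = 100))
  expect_equal(cm$accuracy, 2 / 3)
  perfect <- confusion_matrix(model_labels(), model_labels())
  expect_equal(diag(perfect$percent), rep(100, 3),
               ignore_attr = TRUE)
  set.seed(23)
  truth <- sample(model_labels(), 200, replace = TRUE)
  guess <- sample(model_labels(), 200, replace = TRUE)
  cm2 <- confusion_matrix(truth, guess)
  expect_equal(rowSums(cm2$percent), rep(100, 3), ignore_attr = TRUE)
  expect_error(confusion_matrix(c("A", "C"), c("A", "A"),
                                labels = c("A", "B")), "unknown label")
})

test_that("calibration bins round to the nearest 10% and track accuracy", {
  ct <- calibration_curve(c(0.94, 0.67, 0.12), c(TRUE, TRUE, FALSE))
  got <- ct$bins[ct$bins$count > 0, "confidence"]
  expect_equal(got, c(10, 70, 90))
  # half-way values round away from zero
  ct45 <- calibration_curve(0.45, TRUE)
  expect_equal(ct45$bins[ct45$bins$count > 0, "confidence"], 50)
  # all certain and correct: single bin at 100 with accuracy 100
  ct1 <- calibration_curve(rep(1, 5), rep(TRUE, 5))
  expect_equal(ct1$bins[ct1$bins$count > 0, "confidence"], 100)
  expect_equal(ct1$bins[11, "accuracy"], 100)
  expect_equal(ct1$accuracy, 100)
  # a calibrated source: per-bin accuracy within 3 binomial SEs
  set.seed(24)
  p <- runif(4000, 0.3, 1)
  correct <- rbinom(4000, 1, p)
  ct2 <- calibration_curve(p, correct)
  for (r in which(ct2$bins$count > 20)) {
    pc <- ct2$bins$confidence[r] / 100
    se <- sqrt(pc * (1 - pc) / ct2$bins$count[r]) * 100
    # bin centers are +-5% wide, so allow the half-width too
    expect_lt(abs(ct2$bins$accuracy[r] - ct2$bins$confidence[r]),
              3 * se + 5)
  }
})

test_that("nested-model fits: hyperboloid matches hyperbolic likelihood, BIC may not", {
  mcq <- mcq_design()
  set.seed(25)
  cfg <- mcmc_config(n_chains = 2, n_iter = 1500, n_burn = 600, seed = 26)
  logl_h <- logl_b <- bic_h <- bic_b <- numeric(8)
  for (i in 1:8) {
    pars <- list(k = exp(rnorm(1, -4, 1)), m = exp(rnorm(1, 1, 1)))
    resp <- simulate_participant("hyperbolic", pars, mcq)
    fh <- fit_individual("hyperbolic", mcq, resp, config = cfg)
    fb <- fit_individual("hyperboloid", mcq, resp, config = cfg,
                         hyperboloid_form = "payoff_scaled")
    logl_h[i] <- max(fh$loglik); logl_b[i] <- max(fb$loglik)
    bic_h[i] <- information_criteria(logl_h[i], 2, 27)[["BIC"]]
    bic_b[i] <- information_criteria(logl_b[i], 3, 27)[["BIC"]]
  }
  # the richer nested model never fits meaningfully worse ...
  expect_true(all(logl_b >= logl_h - 0.15))
  # ... but the BIC penalty reverses the ordering for most participants
  expect_gt(mean(bic_h < bic_b), 0.5)
})
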