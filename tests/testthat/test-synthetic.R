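test_that("prior draws match the stated distributions", {
  pr <- sample_prior("hyperbolic", 1e5, seed = 11)
  # log k ~ N(-5, 3): sample mean within 3 standard errors
  expect_lt(abs(mean(log(pr$k)) + 5), 3 * 3 / sqrt(1e5))
  expect_lt(abs(mean(log(pr$m)) - 1), 3 * 5 / sqrt(1e5))
  expect_lt(abs(sd(log(pr$k)) - 3), 0.05)
  hb <- sample_prior("hyperboloid", 2e4, seed = 12)
  expect_true(all(hb$s > 0))
  dd <- sample_prior("direct_difference", 2e4, seed = 13)
  expect_true(all(dd$u > 0) && all(dd$v > 0))
  expect_true(all(dd$w >= 0 & dd$w <= 1))
  expect_lt(abs(mean(dd$w) - 0.5), 3 * sqrt(1 / 12) / sqrt(2e4))
  # determinism
  expect_identical(sample_prior("hyperboloid", 100, seed = 14),
                   sample_prior("hyperboloid", 100, seed = 14))
})

test_that("bundled MCQ loads with its invariants; bad files error", {
  d <- mcq_design()
  expect_s3_class(d, "itc_design")
  expect_identical(nrow(d), 27L)
  expect_true(all(d$t_ss == 0))
  expect_true(all(d$x_ll > d$x_ss))
  expect_identical(attr(d, "design_kind"), "mcq_fixed")
  # round-trip through a written copy preserves all values exactly
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(item = 1:27, x_ss = d$x_ss, x_ll = d$x_ll,
                       t_ll_days = d$t_ll), tmp, row.names = FALSE)
  expect_equal(as.data.frame(load_mcq_design(tmp)), as.data.frame(d))
  # wrong row count
  write.csv(data.frame(item = 1:26, x_ss = d$x_ss[-1], x_ll = d$x_ll[-1],
                       t_ll_days = d$t_ll[-1]), tmp, row.names = FALSE)
  expect_error(load_mcq_design(tmp), "27 rows")
  # non-monotone payoffs
  bad <- data.frame(item = 1:27, x_ss = d$x_ss, x_ll = d$x_ll,
                    t_ll_days = d$t_ll)
  bad$x_ll[3] <- bad$x_ss[3]
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_mcq_design(tmp), "x_ll")
})

test_that("variable designs follow the stimulus distributions", {
  set.seed(15)
  des <- lapply(1:120, function(i) generate_variable_design())
  nt <- vapply(des, nrow, integer(1))
  expect_true(all(nt >= 20 & nt <= 200))
  all_trials <- do.call(rbind, lapply(des, as.data.frame))
  expect_true(all(all_trials$x_ll > all_trials$x_ss))
  expect_true(all(all_trials$t_ll > all_trials$t_ss))
  n <- nrow(all_trials)
  # payoff gap ~ Gamma(shape 2, scale 15): mean 30, sd sqrt(450)
  gap <- all_trials$x_ll - all_trials$x_ss
  expect_lt(abs(mean(gap) - 30), 3 * sqrt(450) / sqrt(n))
  # t_ss ~ Gamma(1, 30): mean 30; delay gap ~ Gamma(2, 30): mean 60
  expect_lt(abs(mean(all_trials$t_ss) - 30), 3 * 30 / sqrt(n))
  expect_lt(abs(mean(all_trials$t_ll - all_trials$t_ss) - 60),
            3 * sqrt(2 * 900) / sqrt(n))
  expect_lt(abs(mean(all_trials$x_ss) - 52.5), 3 * 27.4 / sqrt(n))
  # determinism from the seed
  expect_equal(generate_variable_design(99), generate_variable_design(99))
})

test_that("simulated choice frequencies match the analytic probability", {
  pr <- data.frame(x_ss = 25, t_ss = 0, x_ll = 60, t_ll = 14)
  pars <- list(k = 0.05, m = 0.9)
  p <- choice_prob("hyperbolic", pars, pr)
  one_design <- pr[rep(1, 1e4), ]
  set.seed(16)
  resp <- simulate_participant("hyperbolic", pars, one_design)
  expect_lt(abs(mean(resp) - p), 3 * sqrt(p * (1 - p) / 1e4))
  # deterministic limit: huge m reproduces the argmax of values
  det <- simulate_participant("hyperbolic", list(k = 0.05, m = 1e9),
                              mcq_design(), seed = 17)
  v_ll <- hyperbolic_value(mcq_design()$x_ll, mcq_design()$t_ll, 0.05)
  expect_identical(det, as.integer(v_ll > mcq_design()$x_ss))
  expect_identical(
    simulate_participant("hyperbolic", pars, pr, seed = 18),
    simulate_participant("hyperbolic", pars, pr, seed = 18))
})

test_that("dataset generation is stratified, aligned and reproducible", {
  ds <- generate_dataset(n_per_model = 1000, design = "mcq",
                         split = c(train = .8, validation = .1, test = .1),
                         seed = 19)
  expect_identical(n_participants(ds), 3000L)
  tab <- table(ds$model, ds$split)
  expect_true(all(tab == matrix(c(800, 100, 100), 3, 3, byrow = TRUE)))
  expect_identical(dim(ds$responses), c(3000L, 27L))
  # true parameters are retained and respect each model's support
  dd <- ds$params[ds$model == "direct_difference", ]
  expect_true(all(!is.na(dd$u)) && all(is.na(dd$k)))
  # reproducible as a pure function of (config, seed)
  ds2 <- generate_dataset(n_per_model = 1000, design = "mcq",
                          split = c(train = .8, validation = .1, test = .1),
                          seed = 19)
  expect_identical(ds$responses, ds2$responses)
  expect_identical(ds$params, ds2$params)
  # any participant is reproducible in isolation from its substream
  i <- 42L
  set.seed(ds$participant_seed[i])
  mo <- as.character(ds$model[i])
  r <- simulate_participant(mo, as.list(ds$params[i, param_names(mo)]),
                            mcq_design())
  expect_identical(as.integer(ds$responses[i, ]), r)
})

test_that("variable-design datasets align designs with responses", {
  ds <- generate_dataset(n_per_model = 40, design = "variable", seed = 20)
  expect_identical(length(ds$designs), 120L)
  nt <- vapply(ds$designs, nrow, integer(1))
  expect_identical(lengths(ds$responses), nt)
  sub <- dataset_subset(ds, "test")
  expect_identical(length(sub$responses), length(sub$model))
})

test_that("larger-later choice rate is monotone in the generative parameters", {
  ds <- small_mcq_dataset()
  hy <- dataset_subset(ds, ds$model == "hyperbolic")
  rate <- rowMeans(hy$responses)
  dec <- cut(log(hy$params$k), quantile(log(hy$params$k), 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  by_dec <- tapply(rate, dec, mean)
  expect_lt(cor(seq_along(by_dec), by_dec, method = "spearman"), -0.9)
  dd <- dataset_subset(ds, ds$model == "direct_difference")
  dec_w <- cut(dd$params$w, quantile(dd$params$w, 0:10 / 10),
               include.lowest = TRUE, labels = FALSE)
  by_w <- tapply(rowMeans(dd$responses), dec_w, mean)
  expect_gt(cor(seq_along(by_w), by_w, method = "spearman"), 0.9)
})
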