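test_that("input encodings are validated and invertible", {
  expect_equal(encode_mcq_input(rep(0, 27)), matrix(0, 1, 27))
  r <- rbinom(27, 1, 0.5)
  expect_equal(drop(encode_mcq_input(r)), as.numeric(r))
  # item order is meaningful: permutations change the encoding
  r2 <- c(r[-1], 1 - r[1])
  expect_false(isTRUE(all.equal(encode_mcq_input(r), encode_mcq_input(r2))))
  expect_error(encode_mcq_input(rep(0, 26)), "27")
  expect_error(encode_mcq_input(c(rep(0, 26), 2)), "binary")

  des <- generate_variable_design(51, n_trials = 30)
  resp <- rbinom(30, 1, 0.5)
  s <- encode_sequence(des, resp)
  expect_identical(dim(s), c(5L, 30L))
  expect_true(all(s[5, ] %in% c(-1, 1)))
  dec <- decode_sequence(s)
  expect_equal(dec$design, as.data.frame(des), ignore_attr = TRUE)
  expect_identical(dec$responses, as.integer(resp))
  expect_error(encode_sequence(des, resp[-1]), "misaligned")
  # the fixed questionnaire encodes with an all-zero t_ss channel
  sm <- encode_sequence(mcq_design(), rep(1, 27))
  expect_identical(dim(sm), c(5L, 27L))
  expect_true(all(sm[2, ] == 0))
})

test_that("feed-forward training learns a simple mapping deterministically", {
  set.seed(52)
  X <- matrix(rbinom(27 * 3000, 1, 0.5), ncol = 27)
  Y <- cbind(rowMeans(X[, 1:13]), rowMeans(X[, 14:27]))
  fit <- itcnet:::mlp_train_cpp(X[1:2500, ], Y[1:2500, ],
                                X[2501:3000, ], Y[2501:3000, ],
                                c(32L, 16L), 0L, 60L, 250L, 2e-3, 1e-7,
                                0, 53L)
  expect_lt(tail(fit$val_loss, 1), 0.002)
  pred <- itcnet:::mlp_predict_cpp(fit$W, fit$b, X[2501:3000, ], 0L)
  expect_gt(cor(pred[, 1], Y[2501:3000, 1]), 0.98)
  # identical seeds give identical weights
  fit2 <- itcnet:::mlp_train_cpp(X[1:2500, ], Y[1:2500, ],
                                 X[2501:3000, ], Y[2501:3000, ],
                                 c(32L, 16L), 0L, 60L, 250L, 2e-3, 1e-7,
                                 0, 53L)
  expect_identical(fit$W, fit2$W)
})

test_that("estimators train, estimate on the natural scale, and error on degenerate targets", {
  ds <- small_mcq_dataset()
  cfg <- training_config(epochs = 60L, seed = 54)
  net <- train_estimator("hyperbolic", ds, cfg)
  expect_s3_class(net, "itc_estimator")
  est <- estimate(net, dataset_subset(ds, ds$model == "hyperbolic" &
                                        ds$split == "test"))
  expect_true(all(est$k > 0) && all(est$m > 0))
  expect_identical(nrow(est), 30L)
  # order preserved: single-row estimates match the batch rows
  te <- dataset_subset(ds, ds$model == "hyperbolic" & ds$split == "test")
  one <- estimate(net, te$responses[3, , drop = FALSE])
  expect_equal(one$k, est$k[3], tolerance = 1e-10)
  # degenerate targets refuse to train
  bad <- ds
  bad$params$k[bad$model == "hyperbolic"] <- 0.01
  expect_error(train_estimator("hyperbolic", bad, cfg), "degenerate")
})

test_that("classifier outputs normalized batch-invariant probabilities", {
  ds <- small_mcq_dataset()
  clf <- train_classifier(ds, training_config(epochs = 40L, seed = 55))
  te <- dataset_subset(ds, "test")
  cl <- classify(clf, te)
  expect_equal(rowSums(cl$prob), rep(1, nrow(cl$prob)), tolerance = 1e-6)
  expect_identical(colnames(cl$prob), model_labels())
  one <- classify(clf, te$responses[5, , drop = FALSE])
  expect_equal(drop(one$prob), cl$prob[5, ], tolerance = 1e-10)
  expect_identical(as.character(one$label), as.character(cl$label[5]))
  # argmax equals the reported winner whenever unique
  expect_identical(as.integer(cl$label),
                   unname(apply(cl$prob, 1, which.max)))
  # unbalanced labels warn
  unb <- dataset_subset(ds, c(which(ds$model == "hyperbolic"),
                              which(ds$model == "hyperboloid")[1:100]))
  expect_warning(train_classifier(unb, training_config(epochs = 2L)),
                 "unbalanced")
})

test_that("dropout sampling yields exchangeable draws; plain networks refuse", {
  ds <- small_mcq_dataset()
  cfg <- training_config(epochs = 80L, seed = 56)
  plain <- train_estimator("hyperbolic", ds, cfg)
  expect_error(sample_posterior(plain, ds$responses[1, ], 100, seed = 57),
               "dropout")
  dnet <- train_estimator("hyperbolic", ds, cfg, dropout = 0.5)
  ps <- sample_posterior(dnet, ds$responses[1, ], n_draws = 3000,
                         seed = 58)
  expect_identical(dim(ps$draws), c(3000L, 2L))
  expect_identical(ps$source, "dropout")
  expect_gt(min(apply(ps$draws, 2, sd)), 0)  # dropout varies the output
  # no sequential dependency: lag-1 autocorrelation is null-level
  for (j in 1:2) {
    z <- ps$draws[, j]
    rho <- cor(z[-1], z[-length(z)])
    expect_lt(abs(rho), 3 / sqrt(length(z)))
  }
  # deterministic given the seed; different seeds decorrelate
  ps2 <- sample_posterior(dnet, ds$responses[1, ], n_draws = 3000,
                          seed = 58)
  expect_identical(ps$draws, ps2$draws)
  # the no-dropout forward pass is a fixed point (all draws identical)
  pt1 <- estimate(dnet, ds$responses[1, , drop = FALSE])
  pt2 <- estimate(dnet, ds$responses[1, , drop = FALSE])
  expect_identical(pt1, pt2)
  # dropout draws scatter around the point estimate
  zpt <- attr(pt1, "transformed")
  expect_lt(abs(mean(ps$draws[, "log_k"]) - zpt[1, "log_k"]),
            3 * sd(ps$draws[, "log_k"]) / sqrt(3000) + 0.25)
})

test_that("network specs validate their contracts", {
  expect_error(network_spec("mcq27", "regression", 0), "n_outputs")
  sp <- network_spec("sequence", "classification", 3)
  expect_identical(sp$lstm_units, 150L)
  expect_identical(sp$dense, c(100L, 80L, 30L))
  expect_error(network_spec("sequence", "regression", 2, dropout = 0.5),
               "dropout")
  cfg <- itcnet:::.resolve_config(training_config(), "mcq27")
  expect_identical(cfg$epochs, 5000L)
  expect_identical(cfg$batch_size, 1000L)
  cfg2 <- itcnet:::.resolve_config(training_config(), "sequence")
  expect_identical(cfg2$epochs, 50L)
})
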