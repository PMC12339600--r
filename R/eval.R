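#' Correlation between true and estimated parameters
#'
#' Pearson correlation per parameter on the transformed scale, the
#' standard recovery score for simulation studies (computed on held-out
#' data by the callers in this package). Correlation is invariant to
#' affine rescaling of the estimates, so it scores ordering and linear
#' association rather than absolute calibration.
#'
#' @param true,estimated Aligned matrices or data frames with matching
#'   column names (transformed-scale parameters).
#' @param source Tag recorded with the report (`"network"`,
#'   `"mcmc_hier"` or `"mcmc_nonhier"`).
#' @return Data frame with columns `parameter`, `r` and `source`;
#'   zero-variance columns get `NA` with a warning.
#' @export
recovery_correlation <- function(true, estimated, source = "network") {
  true <- as.matrix(true)
  estimated <- as.matrix(estimated)
  stopifnot(nrow(true) == nrow(estimated))
  common <- intersect(colnames(true), colnames(estimated))
  if (!length(common)) stop("no common parameter columns", call. = FALSE)
  r <- vapply(common, function(nm) {
    if (sd(true[, nm]) < 1e-12 || sd(estimated[, nm]) < 1e-12) {
      warning("zero-variance column: ", nm)
      return(NA_real_)
    }
    cor(true[, nm], estimated[, nm])
  }, numeric(1))
  data.frame(parameter = common, r = as.numeric(r), source = source,
             row.names = NULL)
}

#' Correlation matrix of posterior draws
#'
#' @param samples A [posterior_samples()] object or draws matrix with
#'   at least 100 draws.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
posterior_correlation_matrix <- function(samples) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws
           else as.matrix(samples)
  if (nrow(draws) < 100)
    stop("need at least 100 draws for a stable correlation matrix",
         call. = FALSE)
  cor(draws)
}

.derive_seed <- function(seed, k) {
  (as.integer(seed) * 97L + k * 1009L) %% 2147480009L + 1L
}

#' Model-recovery experiment
#'
#' Simulates balanced held-out participants from the three models and
#' scores how often each inference method identifies the generative
#' model. `"classifier"` trains a softmax network and takes the
#' highest posterior probability; the criterion methods fit all three
#' models to every test participant by MCMC and take the best (highest
#' maximized log-likelihood, or lowest AIC/BIC/DIC/WAIC). Following
#' the two-stage protocol, the criterion fits use as priors the group
#' posterior of a hierarchical fit of a separate batch simulated from
#' each candidate model.
#'
#' Desk-scale defaults (thousands of training simulations, hundreds of
#' test participants, shortened training and chains) are chosen so the
#' full experiment runs in minutes on one CPU while leaving the scored
#' accuracies' plateau behavior intact; the full-scale settings are one
#' configuration away.
#'
#' @param n_per_model Held-out test participants per model.
#' @param methods Subset of `"classifier"`, `"logL"`, `"AIC"`,
#'   `"BIC"`, `"DIC"`, `"WAIC"`.
#' @param design `"mcq"` or `"variable"`.
#' @param seed Master seed; every stage derives its own substream.
#' @param train_per_model,val_per_model Classifier training/validation
#'   simulations per model.
#' @param config Optional [training_config()] for the classifier.
#' @param classifier Optional pre-trained classifier (skips training).
#' @param mcmc [mcmc_config()] for the per-participant criterion fits.
#' @param hier_n Batch size of the hierarchical prior-fitting stage.
#' @param hier_config [mcmc_config()] for the hierarchical stage.
#' @param hyperboloid_fit_form Hyperboloid value function used by the
#'   likelihood-based fits (`"payoff_scaled"` by default: the form that
#'   nests the hyperbolic model, as fit by the likelihood benchmark;
#'   the simulator's canonical hyperboloid remains the normalized
#'   form).
#' @param out_dir Optional directory for a self-contained run record
#'   (config snapshot plus result tables).
#' @return List with per-method `confusion` ([confusion_matrix()]) and
#'   `accuracy`, the classifier and BIC `calibration`
#'   ([calibration_curve()]), the per-participant `metrics` table, the
#'   trained `classifier` and `provenance`.
#' @export
run_model_recovery <- function(n_per_model = 500L,
                               methods = "classifier",
                               design = c("mcq", "variable"),
                               seed = 1L,
                               train_per_model = 20000L,
                               val_per_model = 2500L,
                               config = NULL,
                               classifier = NULL,
                               mcmc = mcmc_config(n_chains = 2L,
                                                  n_iter = 2500L,
                                                  n_burn = 1000L),
                               hier_n = 200L,
                               hier_config = mcmc_config(n_chains = 2L,
                                                         n_iter = 3000L,
                                                         n_burn = 1500L),
                               hyperboloid_fit_form = "payoff_scaled",
                               out_dir = NULL) {
  design <- match.arg(design)
  known <- c("classifier", "logL", "AIC", "BIC", "DIC", "WAIC")
  if (!all(methods %in% known))
    stop("unknown method: ", paste(setdiff(methods, known), collapse = ", "),
         call. = FALSE)
  criterion <- setdiff(methods, "classifier")
  out <- list(provenance = list(seed = seed, n_per_model = n_per_model,
                                design = design, methods = methods))

  need_train <- "classifier" %in% methods && is.null(classifier)
  n_train <- if (need_train) train_per_model else 0L
  n_val <- if (need_train) val_per_model else 0L
  total <- n_train + n_val + n_per_model
  dataset <- generate_dataset(model_labels(), total,
                              design = design,
                              split = c(train = n_train / total,
                                        validation = n_val / total,
                                        test = n_per_model / total),
                              seed = .derive_seed(seed, 1L))
  if (need_train) {
    if (is.null(config)) {
      config <- if (design == "mcq")
        training_config(epochs = 150L, seed = .derive_seed(seed, 2L))
      else
        training_config(epochs = 70L, crop_frac = 0.86,
                        seed = .derive_seed(seed, 2L))
    }
    classifier <- train_classifier(dataset, config)
  }
  test <- dataset_subset(dataset, "test")
  truth <- as.character(test$model)
  n_test <- length(truth)

  results <- list()
  if ("classifier" %in% methods) {
    cl <- classify(classifier, test)
    results$classifier <- list(
      confusion = confusion_matrix(truth, as.character(cl$label)),
      accuracy = mean(as.character(cl$label) == truth))
    conf <- cl$prob[cbind(seq_len(n_test),
                          max.col(cl$prob, ties.method = "first"))]
    out$calibration_classifier <- calibration_curve(
      conf, as.character(cl$label) == truth)
    # average posterior probability assigned to the true model
    out$mean_prob_true_classifier <-
      mean(cl$prob[cbind(seq_len(n_test),
                         match(truth, colnames(cl$prob)))])
    out$classifier <- classifier
  }

  if (length(criterion)) {
    # stage 1: group-level priors from hierarchical fits per model
    group_priors <- list()
    for (mi in seq_along(model_labels())) {
      mo <- model_labels()[mi]
      hds <- generate_dataset(mo, hier_n, design = design,
                              split = c(train = 0, validation = 0,
                                        test = 1),
                              seed = .derive_seed(seed, 10L + mi))
      hf <- fit_hierarchical(mo, hds,
                             hierarchy = hierarchy_spec(batch_size = hier_n),
                             config = hier_config,
                             hyperboloid_form = hyperboloid_fit_form)
      group_priors[[mo]] <- hf$group_priors
    }
    out$group_priors <- group_priors

    # stage 2: per-participant fits of all three models
    metrics <- vector("list", n_test)
    for (i in seq_len(n_test)) {
      di <- if (test$design_kind == "mcq_fixed") test$designs
            else test$designs[[i]]
      ri <- if (test$design_kind == "mcq_fixed") test$responses[i, ]
            else test$responses[[i]]
      row <- list(participant = i, true_model = truth[i],
                  n_trials = nrow(di))
      for (mo in model_labels()) {
        cfg <- mcmc
        cfg$seed <- .derive_seed(seed, 100L + i * 3L + .model_id(mo))
        fit <- fit_individual(mo, di, ri, priors = group_priors[[mo]],
                              config = cfg, keep_pointwise = TRUE,
                              hyperboloid_form = hyperboloid_fit_form)
        logL <- max(fit$loglik)
        ic <- information_criteria(logL, n_params(mo), nrow(di))
        dic <- fit_dic(fit, di, ri)$DIC
        waic <- compute_waic(fit$pointwise)$WAIC
        row[paste0(c("logL_", "AIC_", "BIC_", "DIC_", "WAIC_"), mo)] <-
          list(logL, ic[["AIC"]], ic[["BIC"]], dic, waic)
      }
      metrics[[i]] <- as.data.frame(row)
    }
    metrics <- do.call(rbind, metrics)
    out$metrics <- metrics

    pick <- function(metric, minimize) {
      cols <- paste0(metric, "_", model_labels())
      m <- as.matrix(metrics[, cols])
      idx <- if (minimize) max.col(-m, ties.method = "first")
             else max.col(m, ties.method = "first")
      model_labels()[idx]
    }
    for (me in criterion) {
      winners <- pick(me, minimize = me != "logL")
      results[[me]] <- list(
        confusion = confusion_matrix(truth, winners),
        accuracy = mean(winners == truth))
    }
    if ("BIC" %in% criterion) {
      bic_m <- as.matrix(metrics[, paste0("BIC_", model_labels())])
      probs <- t(apply(bic_m, 1, bic_posterior_probs))
      conf <- probs[cbind(seq_len(n_test),
                          max.col(probs, ties.method = "first"))]
      winners <- model_labels()[max.col(probs, ties.method = "first")]
      out$calibration_bic <- calibration_curve(conf, winners == truth)
      out$mean_prob_true_bic <-
        mean(probs[cbind(seq_len(n_test), match(truth, model_labels()))])
    }
  }
  out$results <- results
  out$accuracy <- vapply(results, function(x) x$accuracy, numeric(1))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- data.frame(key = c("seed", "n_per_model", "design", "methods"),
                       value = c(seed, n_per_model, design,
                                 paste(methods, collapse = "+")))
    .write_atomic(prov, file.path(out_dir, "config.csv"))
    acc <- data.frame(method = names(out$accuracy),
                      accuracy = as.numeric(out$accuracy))
    .write_atomic(acc, file.path(out_dir, "accuracy.csv"))
    for (me in names(results))
      write_confusion(results[[me]]$confusion,
                      file.path(out_dir, paste0("confusion_", me, ".csv")))
    if (!is.null(out$metrics))
      .write_atomic(out$metrics, file.path(out_dir, "metrics.csv"))
  }
  out
}

#' Group-level posterior recovery experiment
#'
#' Simulates a fresh set of participants from one model's generative
#' prior and compares two routes to the group-level posterior of each
#' parameter: (a) Monte-Carlo-dropout draws from a trained estimator,
#' where each thinned network applied to all participants yields one
#' draw of the across-participant mean; and (b) the group-location
#' posterior of a hierarchical MCMC fit. Both are returned with the
#' true generating distribution for overlay.
#'
#' @param estimator A dropout-capable [train_estimator()] result for
#'   `model`.
#' @param model Model label.
#' @param n_participants Number of fresh synthetic participants.
#' @param n_draws Posterior draws per source.
#' @param seed Master seed.
#' @param hier_config [mcmc_config()] for the hierarchical fits.
#' @param batch_size Hierarchical batch size (participants are fit in
#'   batches of at most this many and the group draws pooled).
#' @return List with `network` and `mcmc` (n_draws x parameters group-
#'   mean draws, transformed scale), `point` (no-dropout estimates),
#'   `truth` (generating prior mean/sd on the transformed scale for
#'   location parameters) and `dataset`.
#' @export
group_posterior_experiment <- function(estimator, model = "hyperbolic",
                                       n_participants = 300L,
                                       n_draws = 5000L, seed = 1L,
                                       hier_config = mcmc_config(
                                         n_chains = 2L, n_iter = 2800L,
                                         n_burn = 1500L),
                                       batch_size = 200L) {
  model <- .match_model(model)
  stopifnot(inherits(estimator, "itc_estimator"),
            estimator$model == model)
  dataset <- generate_dataset(model, n_participants, design = "mcq",
                              split = c(train = 0, validation = 0,
                                        test = 1),
                              seed = .derive_seed(seed, 31L))
  gp <- sample_group_posterior(estimator, dataset$responses,
                               n_draws = n_draws,
                               seed = .derive_seed(seed, 32L))
  # hierarchical route, batched
  n_batches <- ceiling(n_participants / batch_size)
  sizes <- rep(floor(n_participants / n_batches), n_batches)
  sizes[seq_len(n_participants - sum(sizes))] <-
    sizes[seq_len(n_participants - sum(sizes))] + 1
  start <- cumsum(c(0, sizes[-length(sizes)]))
  mcmc_draws <- list()
  for (bi in seq_len(n_batches)) {
    idx <- start[bi] + seq_len(sizes[bi])
    cfg <- hier_config
    cfg$seed <- .derive_seed(seed, 40L + bi)
    hf <- fit_hierarchical(model, dataset_subset(dataset, idx),
                           hierarchy = hierarchy_spec(batch_size = batch_size),
                           config = cfg)
    P <- n_params(model)
    mcmc_draws[[bi]] <- hf$group$draws[, seq_len(P), drop = FALSE]
  }
  mcmc_draws <- do.call(rbind, mcmc_draws)
  set.seed(.derive_seed(seed, 50L))
  take <- if (nrow(mcmc_draws) >= n_draws)
    sample(nrow(mcmc_draws), n_draws) else
    sample(nrow(mcmc_draws), n_draws, replace = TRUE)
  mcmc_draws <- mcmc_draws[take, , drop = FALSE]
  colnames(mcmc_draws) <- sub("^mu_", "", colnames(mcmc_draws))

  spec <- prior_spec(model)
  tnames <- param_names(model, transformed = TRUE)
  truth <- list(mean = setNames(numeric(length(tnames)), tnames),
                sd = setNames(numeric(length(tnames)), tnames))
  set.seed(.derive_seed(seed, 51L))
  for (j in seq_along(tnames)) {
    s <- spec[[param_names(model)[j]]]
    if (s$dist == "lognormal") {
      truth$mean[j] <- s$mean; truth$sd[j] <- s$sd
    } else {
      # truncated-normal / uniform parameters: moments of the
      # transformed generating distribution, by large-sample Monte Carlo
      nat <- param_names(model)[j]
      x <- switch(s$dist,
                  truncnormal = .rtruncnorm_pos(200000, s$mean, s$sd),
                  uniform = runif(200000, s$min, s$max))
      z <- if (nat == "w") qlogis(pmin(pmax(x, 1e-12), 1 - 1e-12)) else log(x)
      truth$mean[j] <- mean(z); truth$sd[j] <- sd(z)
    }
  }
  list(network = gp$group_draws, mcmc = mcmc_draws, point = gp$point,
       truth = truth, dataset = dataset, n_draws = n_draws)
}

#' Full versus restricted direct-difference posteriors
#'
#' Compares the joint dropout posterior of the full three-parameter
#' direct-difference model against a restricted variant with the delay
#' sensitivity frozen (`v = 0.7`, near the group-level mean).
#' Overparameterization shows up as strong posterior correlations
#' between u and v in the full model; freezing v removes that axis and
#' typically collapses the remaining u-w correlation as well.
#'
#' @param full_net Dropout-capable estimator of the full model.
#' @param restricted_net Dropout-capable estimator trained with
#'   `fixed = c(v = 0.7)` (2 outputs).
#' @param responses One participant's 27-bit response vector.
#' @param n_draws Dropout draws per model.
#' @param seed Seed for the dropout masks.
#' @return List with `full` and `restricted` posterior correlation
#'   matrices, the two [posterior_samples()] objects and `fixed_v`.
#' @export
restricted_dd_experiment <- function(full_net, restricted_net, responses,
                                     n_draws = 2000L, seed = 1L) {
  stopifnot(identical(full_net$model, "direct_difference"),
            identical(restricted_net$model, "direct_difference"),
            !is.null(restricted_net$fixed))
  ps_full <- sample_posterior(full_net, responses, n_draws, seed)
  ps_res <- sample_posterior(restricted_net, responses, n_draws,
                             seed + 1L)
  list(full = posterior_correlation_matrix(ps_full),
       restricted = posterior_correlation_matrix(ps_res),
       samples_full = ps_full, samples_restricted = ps_res,
       fixed_v = restricted_net$fixed[["v"]])
}
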