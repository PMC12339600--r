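#' Network architecture specification
#'
#' Two input modes are supported. `"mcq27"` takes the 27-bit response
#' vector of the fixed questionnaire through three fully connected tanh
#' hidden layers of 100, 66 and 33 nodes. `"sequence"` takes a
#' 5-channel sequence of arbitrary length (payoffs, delays, signed
#' choice; see [encode_sequence()]) through an LSTM layer with 150
#' recurrent nodes whose final state feeds ReLU layers of 100, 80 and
#' 30 nodes. Either feeds a linear regression head (one node per
#' estimated parameter) or a 3-way softmax classification head.
#'
#' @param input Input mode, `"mcq27"` or `"sequence"`.
#' @param head `"regression"` or `"classification"`.
#' @param n_outputs Nodes in the head (parameter count, or number of
#'   candidate models).
#' @param hidden Hidden sizes for the `"mcq27"` mode.
#' @param lstm_units,dense Recurrent size and dense chain for the
#'   `"sequence"` mode.
#' @param dropout Dropout probability on the last hidden layer (0
#'   disables). Dropout-capable estimators are a separate build
#'   variant used for Monte-Carlo posterior sampling.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(input = c("mcq27", "sequence"),
                         head = c("regression", "classification"),
                         n_outputs,
                         hidden = c(100L, 66L, 33L),
                         lstm_units = 150L,
                         dense = c(100L, 80L, 30L),
                         dropout = 0) {
  input <- match.arg(input)
  head <- match.arg(head)
  stopifnot(n_outputs >= 1, dropout >= 0, dropout < 1)
  if (dropout > 0 && input == "sequence")
    stop("dropout sampling is implemented for the fixed-input networks",
         call. = FALSE)
  structure(list(input = input, head = head,
                 n_outputs = as.integer(n_outputs),
                 hidden = as.integer(hidden),
                 lstm_units = as.integer(lstm_units),
                 dense = as.integer(dense), dropout = dropout),
            class = "network_spec")
}

#' Training configuration
#'
#' Defaults reproduce the reference settings: Adam optimization, L2
#' weight penalty 1e-7, mini-batches of 1000 and a maximum of 5000
#' epochs for fixed-input networks, 50 epochs for sequence networks
#' (whose mini-batch defaults to 64 and whose gradients are clipped at
#' global norm 2 for stability). `NULL` entries are resolved per input
#' mode at training time.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param l2 L2 regularization strength.
#' @param learn_rate Adam step size.
#' @param clip Global-norm gradient clip for sequence networks.
#' @param crop_len,crop_frac Crop curriculum for sequence networks:
#'   during the first `crop_frac` of the epochs each training sequence
#'   is replaced by a random contiguous window of 20 to `crop_len`
#'   trials. Trials are exchangeable within a synthetic participant,
#'   so a window is itself a valid shorter session from the same
#'   model; short windows deliver many cheap optimization steps before
#'   the final epochs adapt the recurrent dynamics to full-length
#'   sequences. `crop_len = 0` disables the curriculum.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return Object of class `training_config`.
#' @export
training_config <- function(epochs = NULL, batch_size = NULL, l2 = 1e-7,
                            learn_rate = NULL, clip = 2,
                            crop_len = 60L, crop_frac = 0.7,
                            seed = 1L) {
  stopifnot(crop_frac >= 0, crop_frac <= 1)
  structure(list(epochs = epochs, batch_size = batch_size, l2 = l2,
                 learn_rate = learn_rate, clip = clip,
                 crop_len = as.integer(crop_len), crop_frac = crop_frac,
                 seed = as.integer(seed)),
            class = "training_config")
}

.resolve_config <- function(config, input) {
  stopifnot(inherits(config, "training_config"))
  if (is.null(config$epochs))
    config$epochs <- if (input == "mcq27") 5000L else 50L
  if (is.null(config$batch_size))
    config$batch_size <- if (input == "mcq27") 1000L else 64L
  if (is.null(config$learn_rate))
    config$learn_rate <- if (input == "mcq27") 1e-3 else 2e-3
  stopifnot(config$epochs >= 1, config$batch_size >= 1, config$l2 >= 0,
            config$learn_rate > 0)
  config
}

#' Encode 27-item questionnaire responses as network input
#'
#' The identity encoding: a binary vector (or matrix, participants in
#' rows) in fixed item order. Item position carries the meaning, so no
#' permutation or summary is applied.
#'
#' @param responses Binary vector of length 27, or matrix with 27
#'   columns.
#' @return Numeric matrix, participants x 27.
#' @export
encode_mcq_input <- function(responses) {
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1L)
  if (ncol(responses) != 27L)
    stop("MCQ input must have 27 entries per participant", call. = FALSE)
  if (!all(responses %in% c(0, 1)))
    stop("MCQ input must be binary", call. = FALSE)
  matrix(as.numeric(responses), nrow = nrow(responses))
}

#' Encode one participant's task as a 5-channel sequence
#'
#' Channels, in fixed order: smaller-sooner payoff, smaller-sooner
#' delay, larger-later payoff, larger-later delay, choice. Payoffs and
#' delays are scaled by 1/100 so the channels share the order of
#' magnitude of the choice channel; the choice is coded +1 for a
#' larger-later and -1 for a smaller-sooner selection. The scaling is
#' invertible (see [decode_sequence()]).
#'
#' @param design Design data frame.
#' @param responses Binary response vector aligned with `design`.
#' @return Numeric matrix, 5 x n_trials.
#' @export
encode_sequence <- function(design, responses) {
  design <- .as_problems(design)
  if (length(responses) != nrow(design))
    stop("responses and design are misaligned", call. = FALSE)
  if (!all(responses %in% c(0, 1)))
    stop("responses must be binary", call. = FALSE)
  rbind(x_ss = design$x_ss / 100, t_ss = design$t_ss / 100,
        x_ll = design$x_ll / 100, t_ll = design$t_ll / 100,
        choice = ifelse(responses == 1, 1, -1))
}

#' Decode a 5-channel sequence back to a design and responses
#'
#' @param seq_mat Matrix produced by [encode_sequence()].
#' @return List with `design` and `responses`.
#' @export
decode_sequence <- function(seq_mat) {
  stopifnot(is.matrix(seq_mat), nrow(seq_mat) == 5L)
  list(design = data.frame(x_ss = seq_mat[1, ] * 100,
                           t_ss = seq_mat[2, ] * 100,
                           x_ll = seq_mat[3, ] * 100,
                           t_ll = seq_mat[4, ] * 100),
       responses = as.integer(seq_mat[5, ] > 0))
}

.dataset_sequences <- function(dataset, idx = seq_along(dataset$model)) {
  if (dataset$design_kind == "mcq_fixed") {
    lapply(idx, function(i)
      encode_sequence(dataset$designs, dataset$responses[i, ]))
  } else {
    lapply(idx, function(i)
      encode_sequence(dataset$designs[[i]], dataset$responses[[i]]))
  }
}

.train_val_xy <- function(dataset, model) {
  keep <- dataset$model == model
  tr <- which(keep & dataset$split == "train")
  va <- which(keep & dataset$split == "validation")
  if (!length(va)) va <- integer(0)
  list(train = tr, val = va)
}

#' Train a simulation-inversion parameter estimator
#'
#' Fits a network that maps observed choices back onto the generative
#' parameters of one model, by supervised regression on synthetic
#' participants: the network inverts the simulator. Targets are the
#' transformed parameters (log k, log m, log s, log u, log v, logit w),
#' so the back-transformed estimates respect the parameter constraints
#' by construction, and the loss is mean squared error. A separate
#' network is trained per model.
#'
#' @param model Model label the dataset was simulated from.
#' @param dataset An [generate_dataset()] result containing that model.
#' @param config A [training_config()].
#' @param dropout Dropout rate on the last hidden layer; use 0.5 to
#'   build the variant used by [sample_posterior()].
#' @param fixed Optional named numeric of parameters frozen at a known
#'   value (e.g. `c(v = 0.7)` for the restricted direct-difference
#'   model); frozen parameters are dropped from the regression targets
#'   and filled back in by [estimate()].
#' @return Object of class `itc_estimator` with the trained weights,
#'   the architecture and training configuration, the prior under
#'   which the training set was simulated (estimates are posterior
#'   summaries under that prior) and the per-epoch training log.
#' @export
train_estimator <- function(model, dataset, config = training_config(),
                            dropout = 0, fixed = NULL) {
  model <- .match_model(model)
  input <- if (dataset$design_kind == "mcq_fixed") "mcq27" else "sequence"
  config <- .resolve_config(config, input)
  tnames <- param_names(model, transformed = TRUE)
  if (!is.null(fixed)) {
    drop_t <- ifelse(names(fixed) == "w", "logit_w",
                     paste0("log_", names(fixed)))
    tnames <- setdiff(tnames, drop_t)
  }
  idx <- .train_val_xy(dataset, model)
  if (!length(idx$train)) stop("dataset has no training rows for ", model,
                               call. = FALSE)
  sub_tr <- dataset_subset(dataset, idx$train)
  sub_va <- dataset_subset(dataset, idx$val)
  Ytr <- transform_params(model, sub_tr$params[, param_names(model)])
  Yva <- transform_params(model, sub_va$params[, param_names(model)])
  Ytr <- Ytr[, tnames, drop = FALSE]
  Yva <- Yva[, tnames, drop = FALSE]
  if (any(apply(Ytr, 2, sd) < 1e-12))
    stop("degenerate dataset: constant regression target", call. = FALSE)
  spec <- network_spec(input, "regression", length(tnames),
                       dropout = dropout)
  if (input == "mcq27") {
    Xtr <- encode_mcq_input(sub_tr$responses)
    Xva <- encode_mcq_input(sub_va$responses)
    fit <- mlp_train_cpp(Xtr, Ytr, Xva, Yva, spec$hidden, 0L,
                         config$epochs, config$batch_size,
                         config$learn_rate, config$l2, spec$dropout,
                         config$seed)
  } else {
    str <- .dataset_sequences(dataset, idx$train)
    sva <- .dataset_sequences(dataset, idx$val)
    fit <- lstm_train_cpp(str, Ytr, sva, Yva, spec$lstm_units, spec$dense,
                          0L, config$epochs, config$batch_size,
                          config$learn_rate, config$l2, config$clip,
                          config$seed, config$crop_len, config$crop_frac)
  }
  structure(list(model = model, spec = spec, config = config,
                 weights = fit[setdiff(names(fit),
                                       c("train_loss", "val_loss"))],
                 target_names = tnames, fixed = fixed,
                 prior = prior_spec(model),
                 log = data.frame(epoch = seq_len(config$epochs),
                                  train_loss = fit$train_loss,
                                  val_loss = fit$val_loss)),
            class = "itc_estimator")
}

.net_forward <- function(net, X_or_seqs, task) {
  if (net$spec$input == "mcq27") {
    mlp_predict_cpp(net$weights$W, net$weights$b, X_or_seqs, task)
  } else {
    lstm_predict_cpp(net$weights, X_or_seqs, task,
                     net$config$batch_size)
  }
}

.estimator_inputs <- function(net, data) {
  if (inherits(data, "itc_dataset")) {
    if (net$spec$input == "mcq27") {
      if (data$design_kind != "mcq_fixed")
        stop("network expects fixed-questionnaire input", call. = FALSE)
      encode_mcq_input(data$responses)
    } else {
      .dataset_sequences(data)
    }
  } else if (net$spec$input == "mcq27") {
    encode_mcq_input(data)
  } else if (is.list(data)) {
    data
  } else {
    stop("sequence networks need a list of encoded sequences or a dataset",
         call. = FALSE)
  }
}

#' Point estimates from a trained estimator
#'
#' Runs the network forward (without dropout) and back-transforms the
#' outputs to the natural scale, so every estimate satisfies the
#' parameter constraints (`k, m, s, u, v > 0`; `0 < w < 1`).
#'
#' @param network An [train_estimator()] result.
#' @param data Response matrix (fixed input), list of encoded
#'   sequences, or an `itc_dataset`.
#' @return Data frame of natural-scale estimates, one row per input,
#'   with the transformed-scale estimates in attribute
#'   `"transformed"`. Parameters frozen at training time are returned
#'   at their fixed value.
#' @export
estimate <- function(network, data) {
  stopifnot(inherits(network, "itc_estimator"))
  X <- .estimator_inputs(network, data)
  Z <- .net_forward(network, X, 0L)
  colnames(Z) <- network$target_names
  full <- param_names(network$model, transformed = TRUE)
  if (!is.null(network$fixed)) {
    Zfull <- matrix(NA_real_, nrow(Z), length(full),
                    dimnames = list(NULL, full))
    Zfull[, network$target_names] <- Z
    for (nm in names(network$fixed)) {
      tz <- if (nm == "w") qlogis(network$fixed[[nm]])
            else log(network$fixed[[nm]])
      Zfull[, ifelse(nm == "w", "logit_w", paste0("log_", nm))] <- tz
    }
    Z <- Zfull
  }
  out <- untransform_params(network$model, Z)
  attr(out, "transformed") <- Z
  out
}

#' Train a model-comparison classifier
#'
#' Treats model comparison as classification: the network maps observed
#' choices onto a softmax posterior probability over the three
#' candidate models, having been trained on data simulated from each
#' of them in equal numbers (equal prior model probabilities). The
#' loss is cross-entropy over the three mutually exclusive labels.
#'
#' @param dataset A balanced 3-model [generate_dataset()] result.
#' @param config A [training_config()].
#' @return Object of class `itc_classifier`.
#' @export
train_classifier <- function(dataset, config = training_config()) {
  input <- if (dataset$design_kind == "mcq_fixed") "mcq27" else "sequence"
  config <- .resolve_config(config, input)
  labs <- model_labels()
  tr <- which(dataset$split == "train")
  va <- which(dataset$split == "validation")
  counts <- table(dataset$model[tr])
  if (length(unique(counts)) != 1L)
    warning("training labels are unbalanced; classifier probabilities ",
            "assume equal prior model probabilities")
  onehot <- function(idx) {
    Y <- matrix(0, length(idx), 3L,
                dimnames = list(NULL, labs))
    Y[cbind(seq_along(idx), as.integer(dataset$model[idx]))] <- 1
    Y
  }
  spec <- network_spec(input, "classification", 3L)
  if (input == "mcq27") {
    fit <- mlp_train_cpp(encode_mcq_input(dataset$responses[tr, , drop = FALSE]),
                         onehot(tr),
                         encode_mcq_input(dataset$responses[va, , drop = FALSE]),
                         onehot(va), spec$hidden, 1L, config$epochs,
                         config$batch_size, config$learn_rate, config$l2,
                         0, config$seed)
  } else {
    fit <- lstm_train_cpp(.dataset_sequences(dataset, tr), onehot(tr),
                          .dataset_sequences(dataset, va), onehot(va),
                          spec$lstm_units, spec$dense, 1L, config$epochs,
                          config$batch_size, config$learn_rate, config$l2,
                          config$clip, config$seed, config$crop_len,
                          config$crop_frac)
  }
  structure(list(spec = spec, config = config,
                 weights = fit[setdiff(names(fit),
                                       c("train_loss", "val_loss"))],
                 labels = labs,
                 log = data.frame(epoch = seq_len(config$epochs),
                                  train_loss = fit$train_loss,
                                  val_loss = fit$val_loss)),
            class = "itc_classifier")
}

#' Posterior model probabilities and winning model
#'
#' Applies a trained classifier; rows are independent (each input is
#' classified on its own, regardless of batch composition). Exact
#' probability ties are broken in favor of the earlier model in the
#' canonical ordering.
#'
#' @param classifier An [train_classifier()] result.
#' @param data Response matrix, list of encoded sequences, or an
#'   `itc_dataset`.
#' @return List with `prob` (matrix of posterior model probabilities,
#'   columns in canonical order) and `label` (factor of winners).
#' @export
classify <- function(classifier, data) {
  stopifnot(inherits(classifier, "itc_classifier"))
  net <- structure(list(spec = classifier$spec, config = classifier$config,
                        weights = classifier$weights),
                   class = "itc_estimator")
  X <- .estimator_inputs(net, data)
  P <- .net_forward(net, X, 1L)
  colnames(P) <- classifier$labels
  win <- apply(P, 1, which.max)  # first max = canonical-order tie-break
  list(prob = P,
       label = factor(classifier$labels[win], levels = classifier$labels))
}

#' Draw posterior samples by Monte-Carlo dropout
#'
#' Applies a dropout-built estimator many times with the dropout layer
#' active; each pass knocks out a random half of the last hidden layer,
#' so repeated applications trace out a posterior distribution over
#' parameters (the posterior of a deep Gaussian process). Draws are
#' independent across passes: there is no chain, no burn-in and no
#' autocorrelation.
#'
#' @param network A dropout-capable [train_estimator()] result.
#' @param responses A single participant's input: 27-bit vector for
#'   fixed-input networks.
#' @param n_draws Number of forward passes (default 5000).
#' @param seed Seed for the dropout masks.
#' @return Object of class `posterior_samples`: list with `draws`
#'   (n_draws x parameters, transformed scale), `param_names` and
#'   `source = "dropout"`.
#' @export
sample_posterior <- function(network, responses, n_draws = 5000L,
                             seed = 1L) {
  stopifnot(inherits(network, "itc_estimator"))
  if (network$spec$dropout <= 0)
    stop("network was built without a dropout layer; train with ",
         "`dropout = 0.5` to enable posterior sampling", call. = FALSE)
  X <- encode_mcq_input(responses)
  cube <- mlp_dropout_predict_cpp(network$weights$W, network$weights$b,
                                  X, 0L, network$spec$dropout,
                                  as.integer(n_draws), as.integer(seed))
  draws <- matrix(cube[, 1L, ], nrow = dim(cube)[1])
  colnames(draws) <- network$target_names
  posterior_samples(draws, source = "dropout")
}

#' Group-level dropout posterior for a whole dataset
#'
#' One dropout draw instantiates a single thinned network applied to
#' every participant; the per-draw mean across participants is one
#' draw from the group-level posterior of each parameter.
#'
#' @inheritParams sample_posterior
#' @param responses Response matrix (participants x 27).
#' @return List with `group_draws` (n_draws x parameters: across-
#'   participant means per draw, transformed scale) and `point`
#'   (no-dropout point estimates, transformed scale).
#' @export
sample_group_posterior <- function(network, responses, n_draws = 5000L,
                                   seed = 1L) {
  stopifnot(inherits(network, "itc_estimator"))
  if (network$spec$dropout <= 0)
    stop("network lacks a dropout layer", call. = FALSE)
  X <- encode_mcq_input(responses)
  cube <- mlp_dropout_predict_cpp(network$weights$W, network$weights$b,
                                  X, 0L, network$spec$dropout,
                                  as.integer(n_draws), as.integer(seed))
  gd <- apply(cube, c(1, 3), mean)
  colnames(gd) <- network$target_names
  pt <- .net_forward(network, X, 0L)
  colnames(pt) <- network$target_names
  list(group_draws = gd, point = pt)
}

#' Container for posterior draws
#'
#' @param draws Matrix, draws x parameters, on the transformed scale.
#' @param source `"dropout"` or `"mcmc"`.
#' @param chain Optional chain index per draw (MCMC provenance).
#' @param logpost Optional joint log-density per draw.
#' @return Object of class `posterior_samples`.
#' @export
posterior_samples <- function(draws, source = c("dropout", "mcmc"),
                              chain = NULL, logpost = NULL) {
  source <- match.arg(source)
  stopifnot(is.matrix(draws), all(is.finite(draws)))
  structure(list(draws = draws, param_names = colnames(draws),
                 source = source, n_draws = nrow(draws),
                 chain = chain, logpost = logpost),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d draws x %d parameters (%s)\n",
              x$n_draws, ncol(x$draws), x$source))
  print(round(rbind(mean = colMeans(x$draws),
                    sd = apply(x$draws, 2, sd)), 3))
  invisible(x)
}

#' @export
print.itc_estimator <- function(x, ...) {
  cat(sprintf("<itc_estimator> %s model, %s input, %d outputs%s\n",
              x$model, x$spec$input, x$spec$n_outputs,
              if (x$spec$dropout > 0)
                sprintf(", dropout %.2f", x$spec$dropout) else ""))
  invisible(x)
}

#' @export
print.itc_classifier <- function(x, ...) {
  cat(sprintf("<itc_classifier> %s input, 3-way softmax\n", x$spec$input))
  invisible(x)
}
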