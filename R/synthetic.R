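#' Prior specification for a model's parameters
#'
#' The priors used both to simulate synthetic participants and as the
#' (matching) priors of the non-hierarchical Bayesian fits:
#'
#' * hyperbolic / hyperboloid: `log(k) ~ Normal(-5, 3)` and
#'   `log(m) ~ Normal(1, 5)` (mean, SD), a deliberately wide net over
#'   discounting rates and choice variability;
#' * hyperboloid adds `s ~ Normal(0.8, 0.3)` truncated to `s > 0`;
#' * direct difference: `u ~ Normal(0.8, 0.3)` and
#'   `v ~ Normal(0.8, 0.3)`, both truncated to positive values, and
#'   `w ~ Uniform(0, 1)`.
#'
#' Second arguments of the normals are standard deviations.
#'
#' @param model Model label.
#' @return Named list (one element per natural-scale parameter) of
#'   descriptors with fields `dist` (`"lognormal"`, `"truncnormal"` or
#'   `"uniform"`), `mean`/`sd` or `min`/`max`.
#' @export
prior_spec <- function(model) {
  model <- .match_model(model)
  ln <- function(mean, sd) list(dist = "lognormal", mean = mean, sd = sd)
  tn <- function(mean, sd) list(dist = "truncnormal", mean = mean, sd = sd)
  un <- function(min, max) list(dist = "uniform", min = min, max = max)
  switch(model,
    hyperbolic = list(k = ln(-5, 3), m = ln(1, 5)),
    hyperboloid = list(k = ln(-5, 3), m = ln(1, 5), s = tn(0.8, 0.3)),
    direct_difference = list(u = tn(0.8, 0.3), v = tn(0.8, 0.3),
                             w = un(0, 1)))
}

.rtruncnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Draw parameters from a model's prior
#'
#' Truncated normals are drawn by rejection, so every draw satisfies
#' the positivity constraints of the target parameter.
#'
#' @param model Model label.
#' @param n Number of draws (participants).
#' @param seed Optional integer seed.
#' @return Data frame of natural-scale parameters, `n` rows.
#' @export
sample_prior <- function(model, n, seed = NULL) {
  model <- .match_model(model)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  spec <- prior_spec(model)
  out <- lapply(spec, function(s) {
    switch(s$dist,
      lognormal = exp(rnorm(n, s$mean, s$sd)),
      truncnormal = .rtruncnorm_pos(n, s$mean, s$sd),
      uniform = runif(n, s$min, s$max))
  })
  as.data.frame(out)
}

#' Simulate one synthetic participant
#'
#' Draws an independent Bernoulli response per trial with probability
#' [choice_prob()]; 1 codes a larger-later choice.
#'
#' @param model Model label.
#' @param params Named natural-scale parameters.
#' @param design Design data frame (`x_ss`, `t_ss`, `x_ll`, `t_ll`).
#' @param seed Optional integer seed.
#' @return Integer vector of 0/1 responses, one per trial.
#' @export
simulate_participant <- function(model, params, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- choice_prob(model, params, design)
  rbinom(length(p), 1L, p)
}

.split_counts <- function(n, fractions) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  counts <- floor(n * fractions)
  counts[1] <- counts[1] + (n - sum(counts))
  counts
}

#' Generate a synthetic dataset of simulated participants
#'
#' The data factory behind every experiment in the package: draws
#' parameters from each requested model's prior, simulates trial-level
#' responses on either the fixed 27-item questionnaire or freshly
#' generated variable-length designs, and tags stratified
#' train/validation/test splits (equal counts per model in every
#' split). One master seed spawns a deterministic per-participant
#' substream, so any participant can be re-simulated in isolation from
#' its stored `participant_seed`.
#'
#' @param models Model label(s) to simulate from.
#' @param n_per_model Participants per model.
#' @param design `"mcq"` for the fixed questionnaire or `"variable"`
#'   for per-participant randomized designs (20-200 trials).
#' @param split Fractions for train/validation/test (must sum to 1).
#' @param seed Master seed.
#' @return Object of class `itc_dataset`: list with `model` (factor),
#'   `params` (natural-scale data frame, `NA` for parameters a model
#'   lacks), `responses` (matrix for the fixed design, list otherwise),
#'   `designs` (shared `itc_design` or per-participant list), `split`
#'   (factor), `participant_seed`, `design_kind` and `seed`.
#' @export
generate_dataset <- function(models = model_labels(), n_per_model,
                             design = c("mcq", "variable"),
                             split = c(train = 0.8, validation = 0.1,
                                       test = 0.1),
                             seed = 1L) {
  design <- match.arg(design)
  models <- vapply(models, .match_model, character(1), USE.NAMES = FALSE)
  set.seed(seed)
  n_total <- n_per_model * length(models)
  all_par <- c("k", "m", "s", "u", "v", "w")
  params <- as.data.frame(matrix(NA_real_, n_total, length(all_par),
                                 dimnames = list(NULL, all_par)))
  label <- character(n_total)
  split_tag <- character(n_total)
  pseed <- integer(n_total)
  row <- 0L
  for (mo in models) {
    pr <- sample_prior(mo, n_per_model)
    idx <- row + seq_len(n_per_model)
    params[idx, names(pr)] <- pr
    label[idx] <- mo
    counts <- .split_counts(n_per_model, split)
    split_tag[idx] <- rep(c("train", "validation", "test"), counts)
    pseed[idx] <- sample.int(.Machine$integer.max - 1L, n_per_model)
    row <- row + n_per_model
  }
  shared <- if (design == "mcq") mcq_design() else NULL
  responses <- vector("list", n_total)
  designs <- if (design == "variable") vector("list", n_total) else shared
  for (i in seq_len(n_total)) {
    set.seed(pseed[i])
    di <- if (design == "mcq") shared else generate_variable_design()
    if (design == "variable") designs[[i]] <- di
    pars <- as.list(params[i, param_names(label[i])])
    responses[[i]] <- simulate_participant(label[i], pars, di)
  }
  if (design == "mcq")
    responses <- do.call(rbind, responses)
  structure(list(
    model = factor(label, levels = model_labels()),
    params = params,
    responses = responses,
    designs = designs,
    split = factor(split_tag, levels = c("train", "validation", "test")),
    participant_seed = pseed,
    design_kind = if (design == "mcq") "mcq_fixed" else "variable",
    seed = seed), class = "itc_dataset")
}

#' @export
print.itc_dataset <- function(x, ...) {
  cat(sprintf("<itc_dataset> %d participants (%s designs), seed %d\n",
              length(x$model), x$design_kind, x$seed))
  print(table(model = x$model, split = x$split))
  invisible(x)
}

#' Number of participants in a dataset
#' @param dataset An `itc_dataset`.
#' @return Integer count.
#' @export
n_participants <- function(dataset) {
  length(dataset$model)
}

#' Subset a dataset by participant index or split
#'
#' @param dataset An `itc_dataset`.
#' @param which Integer/logical participant index, or one of
#'   `"train"`, `"validation"`, `"test"`.
#' @return An `itc_dataset` restricted to the selected participants.
#' @export
dataset_subset <- function(dataset, which) {
  if (is.character(which)) {
    which <- match.arg(which, c("train", "validation", "test"))
    which <- dataset$split == which
  }
  out <- dataset
  out$model <- dataset$model[which]
  out$params <- dataset$params[which, , drop = FALSE]
  out$split <- dataset$split[which]
  out$participant_seed <- dataset$participant_seed[which]
  if (dataset$design_kind == "mcq_fixed") {
    out$responses <- dataset$responses[which, , drop = FALSE]
  } else {
    out$responses <- dataset$responses[which]
    out$designs <- dataset$designs[which]
  }
  out
}

#' True parameters of a dataset on the transformed scale
#'
#' @param dataset An `itc_dataset` whose participants all come from one
#'   model (subset by model first otherwise).
#' @return Matrix of transformed-scale parameters.
#' @export
true_transformed <- function(dataset) {
  mo <- unique(as.character(dataset$model))
  if (length(mo) != 1L)
    stop("dataset mixes models; subset to one model first", call. = FALSE)
  transform_params(mo, dataset$params[, param_names(mo), drop = FALSE])
}
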