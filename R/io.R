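# Atomic delimited-text writes: write to a temporary file in the target
# directory, then rename, so interrupted runs never leave truncated
# tables.
.write_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write.csv(df, tmp, row.names = FALSE)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not write ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write a dataset as trial-level and participant-level tables
#'
#' Two comma-separated files: a trial table with one row per trial
#' (`participant_id, trial, x_ss, t_ss, x_ll, t_ll, choice`) and a
#' participant table with the generative model label, true parameters,
#' split tag and per-participant seed. Writes are atomic.
#'
#' @param dataset An `itc_dataset`.
#' @param trials_path,params_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, trials_path, params_path) {
  stopifnot(inherits(dataset, "itc_dataset"))
  n <- n_participants(dataset)
  rows <- lapply(seq_len(n), function(i) {
    d <- if (dataset$design_kind == "mcq_fixed") dataset$designs
         else dataset$designs[[i]]
    r <- if (dataset$design_kind == "mcq_fixed") dataset$responses[i, ]
         else dataset$responses[[i]]
    data.frame(participant_id = i, trial = seq_len(nrow(d)),
               x_ss = d$x_ss, t_ss = d$t_ss, x_ll = d$x_ll,
               t_ll = d$t_ll, choice = as.integer(r))
  })
  .write_atomic(do.call(rbind, rows), trials_path)
  par <- data.frame(participant_id = seq_len(n),
                    model = as.character(dataset$model),
                    split = as.character(dataset$split),
                    dataset$params,
                    participant_seed = dataset$participant_seed,
                    design_kind = dataset$design_kind,
                    seed = dataset$seed)
  .write_atomic(par, params_path)
  invisible(c(trials_path, params_path))
}

#' Read a dataset from trial-level (and optional participant) tables
#'
#' Validates the trial schema row by row: binary choices, positive
#' payoffs with `x_ll > x_ss`, and `t_ll > t_ss`; errors name the
#' offending file row. With `design = "mcq"` every participant must
#' contribute exactly 27 immediate-vs-delayed items.
#'
#' @param trials_path Trial-level file written by [write_dataset()].
#' @param params_path Optional participant-level file; when present the
#'   full `itc_dataset` (labels, true parameters, splits) is rebuilt.
#' @param design `"auto"`, `"mcq"` or `"variable"`.
#' @return An `itc_dataset` (with `params_path`), else a list with
#'   `designs` and `responses`.
#' @export
read_dataset <- function(trials_path, params_path = NULL,
                         design = c("auto", "mcq", "variable")) {
  design <- match.arg(design)
  tr <- read.csv(trials_path)
  if (nrow(tr) == 0) stop("empty dataset: ", trials_path, call. = FALSE)
  need <- c("participant_id", "trial", "x_ss", "t_ss", "x_ll", "t_ll",
            "choice")
  if (!all(need %in% names(tr)))
    stop("trial file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!(tr$choice %in% c(0, 1)))
  if (length(bad))
    stop("non-binary choice at row ", bad[1], call. = FALSE)
  bad <- which(tr$t_ll <= tr$t_ss)
  if (length(bad))
    stop("t_ll <= t_ss at row ", bad[1], call. = FALSE)
  bad <- which(tr$x_ll <= tr$x_ss)
  if (length(bad))
    stop("x_ll <= x_ss at row ", bad[1], call. = FALSE)

  par <- if (!is.null(params_path)) read.csv(params_path) else NULL
  ids <- unique(tr$participant_id)
  if (design == "auto") {
    design <- if (!is.null(par) && "design_kind" %in% names(par)) {
      if (par$design_kind[1] == "mcq_fixed") "mcq" else "variable"
    } else if (all(tr$t_ss == 0) &&
               all(table(tr$participant_id) == 27L)) "mcq" else "variable"
  }
  split_tr <- split(tr, factor(tr$participant_id, levels = ids))
  if (design == "mcq") {
    nt <- vapply(split_tr, nrow, integer(1))
    bad <- which(nt != 27L)
    if (length(bad))
      stop("participant ", ids[bad[1]], " has ", nt[bad[1]],
           " MCQ rows (expected 27)", call. = FALSE)
    designs <- {
      d1 <- split_tr[[1]][order(split_tr[[1]]$trial), ]
      choice_problems(d1$x_ss, d1$t_ss, d1$x_ll, d1$t_ll,
                      kind = "mcq_fixed")
    }
    responses <- do.call(rbind, lapply(split_tr, function(d)
      as.integer(d$choice[order(d$trial)])))
    dimnames(responses) <- NULL
  } else {
    designs <- lapply(split_tr, function(d) {
      d <- d[order(d$trial), ]
      choice_problems(d$x_ss, d$t_ss, d$x_ll, d$t_ll, kind = "variable")
    })
    names(designs) <- NULL
    responses <- lapply(split_tr, function(d)
      as.integer(d$choice[order(d$trial)]))
    names(responses) <- NULL
  }
  if (is.null(par))
    return(list(designs = designs, responses = responses))

  stopifnot(all(ids %in% par$participant_id))
  par <- par[match(ids, par$participant_id), ]
  all_par <- c("k", "m", "s", "u", "v", "w")
  params <- as.data.frame(matrix(NA_real_, length(ids), length(all_par),
                                 dimnames = list(NULL, all_par)))
  for (nm in intersect(all_par, names(par))) params[[nm]] <- par[[nm]]
  structure(list(
    model = factor(par$model, levels = model_labels()),
    params = params,
    responses = responses,
    designs = designs,
    split = factor(par$split, levels = c("train", "validation", "test")),
    participant_seed = if ("participant_seed" %in% names(par))
      par$participant_seed else rep(NA_integer_, length(ids)),
    design_kind = if (design == "mcq") "mcq_fixed" else "variable",
    seed = if ("seed" %in% names(par)) par$seed[1] else NA_integer_),
    class = "itc_dataset")
}

#' Save a trained network to a versioned binary artifact
#'
#' The artifact embeds the architecture, training configuration,
#' target transforms and the prior the training data were simulated
#' under, so estimates loaded later remain interpretable as posterior
#' summaries under that prior.
#'
#' @param network An `itc_estimator` or `itc_classifier`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, c("itc_estimator", "itc_classifier")))
  obj <- list(format_version = 1L,
              package_version = as.character(utils::packageVersion("itcnet")),
              network = network)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path))
  saveRDS(obj, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Load a network saved by [save_network()]
#' @param path `.rds` path.
#' @return The stored network object.
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unrecognized network artifact format", call. = FALSE)
  obj$network
}
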