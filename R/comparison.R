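#' Akaike and Bayesian information criteria
#'
#' `AIC = 2p - 2 logL`; `BIC = p log(n) - 2 logL`, where `n` counts the
#' trials the participant contributed (27 for the fixed
#' questionnaire). Lower is better.
#'
#' @param logL Maximized log-likelihood.
#' @param p Number of free parameters.
#' @param n Number of trials.
#' @return Named vector with `AIC` and `BIC`.
#' @export
information_criteria <- function(logL, p, n) {
  stopifnot(n >= 1, p >= 1)
  c(AIC = 2 * p - 2 * logL, BIC = p * log(n) - 2 * logL)
}

#' Deviance information criterion
#'
#' Spiegelhalter's form: with per-draw deviance `D = -2 logL`,
#' `p_D = mean(D) - D(posterior mean)` and `DIC = mean(D) + p_D`.
#'
#' @param samples Draws matrix (or [posterior_samples()]).
#' @param deviance_fn Function mapping one parameter draw to its
#'   deviance.
#' @param deviances Optional precomputed per-draw deviances (skips
#'   `deviance_fn` on the draws).
#' @return List with `DIC`, `p_D`, `mean_deviance` and
#'   `deviance_at_mean`.
#' @export
compute_dic <- function(samples, deviance_fn, deviances = NULL) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws
           else as.matrix(samples)
  if (nrow(draws) == 0) stop("no posterior draws", call. = FALSE)
  if (is.null(deviances)) deviances <- apply(draws, 1, deviance_fn)
  dbar <- mean(deviances)
  dhat <- deviance_fn(colMeans(draws))
  p_d <- dbar - dhat
  list(DIC = dbar + p_d, p_D = p_d, mean_deviance = dbar,
       deviance_at_mean = dhat)
}

#' DIC of a fitted participant
#'
#' Convenience wrapper around [compute_dic()] for an [fit_individual()]
#' result, using the stored per-draw log-likelihoods and evaluating the
#' plug-in deviance at the posterior mean of the transformed
#' parameters.
#'
#' @param fit An `itc_fit`.
#' @param design,responses The data the fit was computed on.
#' @return As [compute_dic()].
#' @export
fit_dic <- function(fit, design, responses) {
  stopifnot(inherits(fit, "itc_fit"))
  D <- .design_matrix(design)
  mid <- if (!is.null(fit$model_id)) fit$model_id else .model_id(fit$model)
  dev_fn <- function(z)
    -2 * loglik_point_cpp(mid, D, as.integer(responses), z)
  compute_dic(fit$samples, dev_fn, deviances = -2 * fit$loglik)
}

#' Widely applicable information criterion
#'
#' Variance-based form: `lppd = sum_i log mean_s exp(ll_si)`,
#' `p_waic = sum_i var_s(ll_si)`, `WAIC = -2 (lppd - p_waic)`, where
#' `ll_si` is the log-likelihood of trial `i` under draw `s`.
#'
#' @param pointwise Matrix of pointwise log-likelihoods, draws x
#'   trials.
#' @return List with `WAIC`, `lppd` and `p_waic`.
#' @export
compute_waic <- function(pointwise) {
  pointwise <- as.matrix(pointwise)
  stopifnot(all(is.finite(pointwise)))
  if (nrow(pointwise) == 1L) {
    warning("single draw: p_waic is 0")
    lppd <- sum(pointwise)
    return(list(WAIC = -2 * lppd, lppd = lppd, p_waic = 0))
  }
  # stable log-mean-exp per trial; population-variance penalty so the
  # criterion is invariant to duplicating the draws
  mx <- apply(pointwise, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(pointwise, 2, mx)))))
  p_waic <- sum(apply(pointwise, 2, function(x) mean((x - mean(x))^2)))
  list(WAIC = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Posterior model probabilities from BIC values
#'
#' Approximates the Bayes factor between models by
#' `BF = exp(-(BIC_1 - BIC_2)/2)` and converts to posterior model
#' probabilities under equal prior probabilities (1/3 each):
#' weights proportional to `exp(-(BIC - min BIC)/2)`, normalized.
#' Subtracting any constant from all BICs leaves the result unchanged.
#'
#' @param bic Numeric vector of BIC values (one per model).
#' @return Probability vector summing to 1, names preserved.
#' @export
bic_posterior_probs <- function(bic) {
  stopifnot(all(is.finite(bic)))
  w <- exp(-(bic - min(bic)) / 2)
  w / sum(w)
}

#' Row-normalized confusion matrix
#'
#' Rows are the true (generative) models, columns the inferred models;
#' entries are row percentages, so each row sums to 100. The returned
#' object also carries the column totals (the bias to infer each
#' model) and the overall accuracy (label-weighted diagonal).
#'
#' @param true,inferred Aligned label vectors (factors or characters
#'   over [model_labels()] or any common label set).
#' @param labels Label set and ordering; defaults to the canonical
#'   model ordering when all labels are model labels.
#' @return Object of class `confusion_matrix`: list with `percent`
#'   (matrix), `counts`, `column_total` and `accuracy`.
#' @export
confusion_matrix <- function(true, inferred, labels = NULL) {
  true <- as.character(true)
  inferred <- as.character(inferred)
  stopifnot(length(true) == length(inferred))
  if (is.null(labels)) {
    labels <- if (all(c(true, inferred) %in% model_labels()))
      model_labels() else sort(unique(c(true, inferred)))
  }
  if (!all(c(true, inferred) %in% labels))
    stop("unknown label: ",
         paste(setdiff(unique(c(true, inferred)), labels), collapse = ", "),
         call. = FALSE)
  counts <- table(factor(true, labels), factor(inferred, labels))
  pct <- sweep(counts, 1, pmax(rowSums(counts), 1), "/") * 100
  acc <- sum(diag(counts)) / length(true)
  structure(list(percent = unclass(pct), counts = unclass(counts),
                 column_total = colSums(unclass(pct)),
                 accuracy = acc),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 2, ...) {
  cat("Confusion matrix (rows: true model; columns: inferred; row %)\n")
  m <- rbind(round(x$percent, digits),
             Total = round(x$column_total, digits))
  print(m)
  cat(sprintf("Overall accuracy: %.2f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Calibration table of a probabilistic classifier
#'
#' Bins each decision's confidence (the posterior probability of the
#' chosen model) to the nearest 10% — 11 levels, 0% to 100%, with
#' half-way values rounded away from zero — and tabulates the
#' empirical accuracy at each level. An approach is well calibrated
#' when accuracy tracks confidence across bins.
#'
#' @param prob Confidence of each decision, in \[0, 1\].
#' @param correct Logical (or 0/1) correctness of each decision.
#' @return Object of class `calibration_table`: data frame `bins`
#'   (confidence level, count, accuracy; empty bins flagged with
#'   `NA` accuracy) plus `mean_confidence` and `accuracy` overall.
#' @export
calibration_curve <- function(prob, correct) {
  stopifnot(length(prob) == length(correct),
            all(prob >= 0 & prob <= 1))
  correct <- as.logical(correct)
  # round half away from zero (round() rounds half to even)
  lev <- floor(prob * 10 + 0.5) * 10
  levels_pct <- seq(0, 100, 10)
  count <- vapply(levels_pct, function(l) sum(lev == l), numeric(1))
  acc <- vapply(levels_pct, function(l)
    if (any(lev == l)) mean(correct[lev == l]) * 100 else NA_real_,
    numeric(1))
  structure(list(
    bins = data.frame(confidence = levels_pct, count = count,
                      accuracy = acc),
    mean_confidence = mean(prob) * 100,
    accuracy = mean(correct) * 100),
    class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf(
    "Calibration: mean confidence %.1f%%, overall accuracy %.1f%%\n",
    x$mean_confidence, x$accuracy))
  print(x$bins)
  invisible(x)
}

#' Write a confusion matrix as delimited text
#'
#' Writes the row-normalized percent layout, including the column
#' totals row.
#'
#' @param cm A [confusion_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- rbind(cm$percent, Total = cm$column_total)
  d <- data.frame(true_model = rownames(m), round(m, 4),
                  check.names = FALSE)
  .write_atomic(d, path)
}
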