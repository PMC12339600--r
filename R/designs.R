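#' Construct a design (ordered set of choice problems)
#'
#' A design is a data frame with one smaller-sooner vs larger-later
#' money/delay pair per row. Payoffs are in currency units, delays in
#' days. Invariants: `x_ll > x_ss` on every trial and `t_ll > t_ss`
#' (the bundled questionnaire has `t_ss = 0`).
#'
#' @param x_ss,t_ss Payoff and delay of the smaller-sooner option.
#' @param x_ll,t_ll Payoff and delay of the larger-later option.
#' @param kind Design kind, `"mcq_fixed"` or `"variable"`.
#' @return Data frame of class `itc_design` with columns `x_ss`,
#'   `t_ss`, `x_ll`, `t_ll` and a `design_kind` attribute.
#' @export
choice_problems <- function(x_ss, t_ss, x_ll, t_ll, kind = "variable") {
  kind <- match.arg(kind, c("mcq_fixed", "variable"))
  d <- data.frame(x_ss = as.numeric(x_ss), t_ss = as.numeric(t_ss),
                  x_ll = as.numeric(x_ll), t_ll = as.numeric(t_ll))
  if (any(d$x_ss <= 0) || any(d$x_ll <= 0))
    stop("payoffs must be > 0", call. = FALSE)
  if (any(d$t_ss < 0))
    stop("delays must be >= 0", call. = FALSE)
  bad <- which(d$x_ll <= d$x_ss)
  if (length(bad))
    stop("x_ll must exceed x_ss (violated at row ", bad[1], ")", call. = FALSE)
  bad <- which(d$t_ll <= d$t_ss)
  if (length(bad))
    stop("t_ll must exceed t_ss (violated at row ", bad[1], ")", call. = FALSE)
  if (kind == "mcq_fixed" && nrow(d) != 27L)
    stop("an mcq_fixed design must have exactly 27 items, got ", nrow(d),
         call. = FALSE)
  class(d) <- c("itc_design", "data.frame")
  attr(d, "design_kind") <- kind
  d
}

#' Read a 27-item monetary choice questionnaire from file
#'
#' Expects a comma-separated file with header
#' `item,x_ss,x_ll,t_ll_days` and 27 rows; the smaller-sooner delay is
#' implicitly 0 ("today"). Item order is preserved, since the fixed
#' position of each item is what gives a 27-bit response vector its
#' meaning.
#'
#' @param path Path to the file; defaults to the questionnaire bundled
#'   with the package.
#' @return An `itc_design` with 27 rows and `design_kind`
#'   `"mcq_fixed"`.
#' @export
load_mcq_design <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mcq27.csv", package = "itcnet")
  d <- read.csv(path)
  need <- c("item", "x_ss", "x_ll", "t_ll_days")
  if (!all(need %in% names(d)))
    stop("MCQ file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(d) != 27L)
    stop("MCQ file must have exactly 27 rows, got ", nrow(d), call. = FALSE)
  d <- d[order(d$item), , drop = FALSE]
  choice_problems(d$x_ss, 0, d$x_ll, d$t_ll_days, kind = "mcq_fixed")
}

#' The bundled 27-item monetary choice questionnaire
#'
#' @return An `itc_design` with the 27 fixed items (smaller-sooner
#'   payoff today vs larger-later payoff after 7-186 days).
#' @export
mcq_design <- function() {
  load_mcq_design()
}

#' Generate a variable-length randomized design
#'
#' Draws a design whose stimuli roughly mimic the value ranges of the
#' monetary choice questionnaire while varying freely across trials.
#' Per trial, independently: `x_ss ~ Uniform(5, 100)`,
#' `x_ll = x_ss + Gamma(shape 2, scale 15)` (mean payoff gap 30),
#' `t_ss ~ Gamma(shape 1, scale 30)` (mean 30 days) and
#' `t_ll = t_ss + Gamma(shape 2, scale 30)` (mean gap 60 days). The
#' trial count is uniform on the integers 20 to 200 unless given.
#'
#' @param seed Optional integer seed for reproducibility.
#' @param n_trials Optional fixed trial count (20-200 by default).
#' @return An `itc_design` with `design_kind` `"variable"`.
#' @export
generate_variable_design <- function(seed = NULL, n_trials = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_trials)) n_trials <- sample(20:200, 1L)
  x_ss <- runif(n_trials, 5, 100)
  x_ll <- x_ss + rgamma(n_trials, shape = 2, scale = 15)
  t_ss <- rgamma(n_trials, shape = 1, scale = 30)
  t_ll <- t_ss + rgamma(n_trials, shape = 2, scale = 30)
  choice_problems(x_ss, t_ss, x_ll, t_ll, kind = "variable")
}

#' @export
print.itc_design <- function(x, ...) {
  cat(sprintf("<itc_design> %s, %d trials\n", attr(x, "design_kind"), nrow(x)))
  print(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
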