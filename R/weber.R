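# Log-scale, fixed-variability Weber-fraction model: the error rate for a
# comparison of n_L > n_S dots is the area below zero of a Gaussian with mean
# log(n_L) - log(n_S) and standard deviation sqrt(2) * w.

#' Predicted error rate under the log-scale Weber model
#'
#' The internal magnitudes of the two arrays are modelled as Gaussians on a
#' log scale with common spread `w`; the difference has mean
#' `log(n_l) - log(n_s)` and standard deviation `sqrt(2) * w`, and an error
#' occurs when the difference falls below zero:
#' `0.5 * erfc((log(n_l) - log(n_s)) / (2 * w))` (natural logarithm).
#'
#' @param w Weber fraction, a positive scalar or vector.
#' @param n_l,n_s Larger and smaller numerosities (`n_l > n_s >= 1`).
#' @return Error probability in (0, 0.5).
#' @examples
#' weber_error_rate(0.16, 10, 9)
#' @export
weber_error_rate <- function(w, n_l, n_s) {
  if (any(n_l <= n_s)) stop("n_l must exceed n_s")
  if (any(n_s < 1)) stop("n_s must be >= 1")
  if (any(w <= 0)) stop("w must be positive")
  d <- log(n_l) - log(n_s)
  # lower tail below 0 of N(d, 2 w^2) = erfc(d / (2w)) / 2
  pnorm(-d / (sqrt(2) * w))
}

.weber_nll <- function(w, n_err, n_tot, log_ratio) {
  p <- pnorm(-log_ratio / (sqrt(2) * w))
  -sum(n_err * log(p) + (n_tot - n_err) * log1p(-p))
}

#' Fit the Weber fraction from ratio-wise accuracy
#'
#' Estimates `w` by maximising the product of binomial likelihoods of the
#' observed error counts across the four ratio conditions under
#' [weber_error_rate()], with a bounded golden-section search.
#'
#' @param conditions An `ans_conditions` object from [collapse_conditions()],
#'   or a participant's validated trial data frame.
#' @param lower,upper Search bounds for `w` (defaults 0.01 and 2, bracketing
#'   the plausible adult range with wide margin).
#' @return An object of class `weber_fit` with components `w`, `log_w`,
#'   `predicted_error_rates`, `objective_value` (negative log-likelihood at
#'   the optimum), `accuracy`, `n_trials`, and `boundary`
#'   (`"none"`, `"lower"` for at-ceiling data pinned to `lower`, `"upper"`
#'   for at-chance data pinned to `upper`).
#' @examples
#' trials <- simulate_participant(ddm_params(), seed = 1)
#' fit_weber(trials)
#' @export
fit_weber <- function(conditions, lower = 0.01, upper = 2) {
  if (is.data.frame(conditions)) conditions <- collapse_conditions(conditions)
  if (!inherits(conditions, "ans_conditions"))
    stop("conditions must be an 'ans_conditions' object or a trial data frame")
  n_err <- vapply(conditions, `[[`, 0, "n_error")
  n_tot <- vapply(conditions, function(cc) cc$n_correct + cc$n_error, 0)
  lr <- vapply(conditions, `[[`, 0, "log_ratio")
  if (any(n_tot < 1)) stop("every condition needs at least one trial")

  boundary <- "none"
  if (sum(n_err) == 0) {
    w <- lower
    boundary <- "lower"
    warning("no errors in any condition; w pinned to lower search bound")
  } else if (all(n_err >= n_tot / 2)) {
    w <- upper
    boundary <- "upper"
    warning("at- or below-chance accuracy in all conditions; ",
            "w pinned to upper search bound")
  } else {
    opt <- optimize(.weber_nll, c(lower, upper), n_err = n_err,
                    n_tot = n_tot, log_ratio = lr, tol = 1e-8)
    w <- opt$minimum
    if (w <= lower * 1.001) boundary <- "lower"
    if (w >= upper * 0.999) boundary <- "upper"
  }
  structure(list(
    w = w, log_w = log(w),
    predicted_error_rates = setNames(pnorm(-lr / (sqrt(2) * w)), names(lr)),
    observed_error_rates = setNames(n_err / n_tot, names(lr)),
    objective_value = .weber_nll(w, n_err, n_tot, lr),
    accuracy = 1 - sum(n_err) / sum(n_tot),
    n_trials = sum(n_tot),
    boundary = boundary
  ), class = "weber_fit")
}

#' @export
print.weber_fit <- function(x, digits = 3, ...) {
  cat("Log-scale Weber-fraction fit (binomial ML)\n")
  cat(sprintf("  w = %.*f   log(w) = %.*f   accuracy = %.*f   (n = %d)\n",
              digits, x$w, digits, x$log_w, digits, x$accuracy, x$n_trials))
  tab <- rbind(observed = x$observed_error_rates,
               predicted = x$predicted_error_rates)
  print(round(tab, digits))
  if (x$boundary != "none")
    cat("  note: w pinned at the", x$boundary, "search bound\n")
  invisible(x)
}

#' @export
coef.weber_fit <- function(object, ...) c(w = object$w)

#' @export
logLik.weber_fit <- function(object, ...) {
  structure(-object$objective_value, df = 1L, class = "logLik")
}

#' Predicted error rates for new ratios
#'
#' @param object A `weber_fit`.
#' @param ratios Character vector of design ratios (default all four).
#' @param ... Unused.
#' @return Named vector of predicted error rates at the fitted `w`.
#' @export
predict.weber_fit <- function(object, ratios = ans_ratio_levels(), ...) {
  lr <- vapply(ratios, .ans_log_ratio, 0)
  setNames(pnorm(-lr / (sqrt(2) * object$w)), ratios)
}
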