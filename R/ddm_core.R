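# Diffusion-model predictions under the ANS drift-scale constraint: drift
# rates proportional to the log numerosity ratio, across-trial variability in
# drift (Gaussian, SD eta), starting point (uniform, range sz) and
# non-decision time (uniform, range st), plus a uniform contaminant mixture.

#' Diffusion-model parameter set
#'
#' Constructs and validates the seven free parameters of the ANS diffusion
#' model plus its fixed conventions: the mean starting point `z` is always
#' half the boundary separation, and the within-trial diffusion coefficient
#' `s` is the conventional 0.1 (a gauge, not a substantive parameter).
#' Defaults are typical young-adult values for this task.
#'
#' @param a Boundary separation (evidence units), > 0.
#' @param sz Range of the uniform across-trial starting-point distribution,
#'   `0 <= sz < a`.
#' @param vs Drift scale: evidence per unit log-numerosity-ratio per second.
#' @param eta SD of the Gaussian across-trial drift distribution, >= 0;
#'   shared across the four ratio conditions.
#' @param ter Mean non-decision time in seconds, `ter > st/2`.
#' @param st Range of the uniform non-decision-time distribution, >= 0.
#' @param po Proportion of contaminant trials in [0, 1].
#' @param s Within-trial diffusion coefficient (fixed scaling convention).
#' @return An object of class `ddm_params` (named list including the derived
#'   `z = a/2`).
#' @examples
#' ddm_params()                     # typical adult values
#' ddm_params(a = 0.12, vs = 0.8)   # a more cautious, less acute observer
#' @export
ddm_params <- function(a = 0.093, sz = 0.023, vs = 1.163, eta = 0.167,
                       ter = 0.414, st = 0.219, po = 0.004, s = 0.1) {
  p <- list(a = a, sz = sz, vs = vs, eta = eta, ter = ter, st = st,
            po = po, s = s, z = a / 2)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                  is.finite(v), TRUE)))
    stop("all parameters must be finite numeric scalars")
  if (a <= 0) stop("boundary separation a must be positive")
  if (sz < 0 || sz >= a) stop("starting-point range sz must satisfy 0 <= sz < a")
  if (eta < 0) stop("drift variability eta must be nonnegative")
  if (st < 0 || ter <= st / 2)
    stop("non-decision time must satisfy ter > st/2 >= 0")
  if (po < 0 || po > 1) stop("contaminant proportion po must be in [0, 1]")
  if (s <= 0) stop("diffusion coefficient s must be positive")
  structure(p, class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, digits = 4, ...) {
  cat("Diffusion-model parameters (z = a/2, s =", format(x$s), ")\n")
  v <- unlist(x[c("a", "sz", "vs", "eta", "ter", "st", "po")])
  print(round(v, digits))
  invisible(x)
}

#' @export
as.double.ddm_params <- function(x, ...)
  unlist(x[c("a", "sz", "vs", "eta", "ter", "st", "po")])

#' Drift rate for a numerosity pair
#'
#' The mean drift toward the correct boundary is the log numerosity ratio
#' scaled by the participant's drift scale:
#' `vs * (log(n_l) - log(n_s))`, natural logarithm.
#'
#' @param vs Drift scale.
#' @param n_l,n_s Larger and smaller numerosities (`n_l > n_s`).
#' @return Drift rate in evidence units per second.
#' @examples
#' drift_rate(1.16, 4, 3)   # ~0.33
#' drift_rate(1.16, 10, 9)  # ~0.12
#' @export
drift_rate <- function(vs, n_l, n_s) {
  if (any(n_l <= n_s)) stop("n_l must exceed n_s")
  vs * (log(n_l) - log(n_s))
}

#' Absorption probability at the correct boundary
#'
#' Closed-form probability that a Wiener process with drift `v` and diffusion
#' coefficient `s`, started at `z` between absorbing boundaries 0 and `a`,
#' is absorbed at the upper (correct) boundary. Continuous through `v = 0`
#' (where it equals `z/a`).
#'
#' @param v Drift rate.
#' @param a Boundary separation.
#' @param z Starting point, `0 < z < a`.
#' @param s Diffusion coefficient.
#' @return Probability in (0, 1), vectorized over `v`.
#' @export
absorption_prob <- function(v, a, z = a / 2, s = 0.1) {
  if (z <= 0 || z >= a) stop("starting point z must lie strictly in (0, a)")
  vapply(v, cpp_absorption_prob, 0, a = a, z = z, s = s)
}

#' First-passage-time CDF of the two-boundary Wiener process
#'
#' Defective cumulative first-passage probability through the correct (upper)
#' or error (lower) boundary by time `t`, for a single trial without
#' across-trial variability. As `t` grows the value approaches the
#' corresponding absorption probability. Computed from the eigenfunction
#' series with adaptive truncation to absolute tolerance `tol`.
#'
#' @param t Vector of decision times (seconds), `t >= 0`.
#' @param response `"correct"` (upper boundary) or `"error"` (lower).
#' @param v Drift rate.
#' @param a Boundary separation.
#' @param z Starting point.
#' @param s Diffusion coefficient.
#' @param tol Absolute series tolerance.
#' @param kmax Series term cap; exceeding it is a numerical-convergence error.
#' @return Vector of defective cumulative probabilities.
#' @export
fpt_cdf <- function(t, response = c("correct", "error"), v, a, z = a / 2,
                    s = 0.1, tol = 1e-7, kmax = 50000L) {
  response <- match.arg(response)
  if (any(t < 0)) stop("t must be nonnegative")
  if (z <= 0 || z >= a) stop("starting point z must lie strictly in (0, a)")
  cpp_fpt_cdf(t, response == "correct", v, a, z, s, tol, as.integer(kmax))
}

# quadrature nodes/weights for the across-trial dimensions; degenerate
# dimensions collapse to a single node. Non-decision time is integrated in
# the C++ layer with Gauss-Legendre nodes on [0, 1], rescaled per evaluation
# time to the subinterval where the first-passage CDF is nonzero.
.mixture_nodes <- function(params, v_mean, n_nodes) {
  if (params$eta > 0) {
    gh <- pracma::gaussHermite(n_nodes)
    vn <- v_mean + sqrt(2) * params$eta * gh$x
    vw <- gh$w / sqrt(pi)
  } else { vn <- v_mean; vw <- 1 }
  if (params$sz > 0) {
    gl <- pracma::gaussLegendre(n_nodes, -0.5, 0.5)
    zn <- params$z + params$sz * gl$x
    zw <- gl$w
  } else { zn <- params$z; zw <- 1 }
  g01 <- pracma::gaussLegendre(n_nodes, 0, 1)
  list(vn = vn, vw = vw, zn = zn, zw = zw, gx = g01$x, gw = g01$w)
}

# mixture CDF over the across-trial distributions at RT values t (response
# "correct" maps to the upper boundary); returns defective values
.mixture_cdf <- function(params, v_mean, t_correct, t_error, n_nodes = 13L,
                         tol = 1e-7, kmax = 50000L) {
  nd <- .mixture_nodes(params, v_mean, n_nodes)
  cpp_mixture_cdf(t_correct, t_error, nd$vn, nd$vw, nd$zn, nd$zw,
                  params$ter - params$st / 2, params$ter + params$st / 2,
                  nd$gx, nd$gw, params$a, params$s, tol, kmax)
}

# uniform contaminant CDF on [w0, w1], clamped
.contaminant_cdf <- function(t, window) {
  pmin(1, pmax(0, (t - window[1]) / (window[2] - window[1])))
}

#' Model-predicted choice and RT structure for one ratio condition
#'
#' Integrates the single-trial first-passage quantities over the across-trial
#' distributions of drift (Gaussian, Gauss--Hermite nodes), starting point and
#' non-decision time (uniform, Gauss--Legendre nodes), and mixes in a uniform
#' contaminant process with weight `po`. Contaminant trials keep the
#' diffusion process's response, so the predicted choice probability is
#' unaffected by the contaminant mixture.
#'
#' @param params A [ddm_params()] object.
#' @param ratio One of `"4:3"`, `"7:6"`, `"9:8"`, `"10:9"`.
#' @param cont_window Two-element contaminant RT window in seconds; defaults
#'   to `c(0.2, 3)`, and during fitting is set to the condition's observed RT
#'   range.
#' @param n_nodes Quadrature nodes per non-degenerate dimension (default 13,
#'   at which node doubling moves no bin probability by more than 1e-5; the
#'   objective surface is deterministic by construction).
#' @param tol,kmax Series tolerance and term cap (see [fpt_cdf()]).
#' @return An object of class `ddm_cond_pred` with elements `ratio`,
#'   `drift` (mean drift for the condition), `p_correct`, `cdf(t, response)`
#'   (full mixture CDF of observed RT, defective in `response`),
#'   `quantile(p, response)` (conditional RT quantile), and
#'   `bin_probs(cuts)` giving joint response-by-RT-bin probabilities for
#'   arbitrary cut points.
#' @examples
#' pred <- predict_condition(ddm_params(), "4:3")
#' pred$p_correct
#' pred$quantile(c(0.1, 0.5, 0.9), "correct")
#' @export
predict_condition <- function(params, ratio = ans_ratio_levels(),
                              cont_window = c(0.2, 3), n_nodes = 13L,
                              tol = 1e-7, kmax = 50000L) {
  ratio <- match.arg(ratio)
  stopifnot(inherits(params, "ddm_params"))
  if (length(cont_window) != 2L || cont_window[2] <= cont_window[1])
    stop("cont_window must be an increasing pair of RTs")
  v <- params$vs * .ans_log_ratio(ratio)
  po <- params$po

  base <- .mixture_cdf(params, v, numeric(0), numeric(0), n_nodes, tol, kmax)
  p_correct <- base$p_upper

  cdf <- function(t, response = c("correct", "error")) {
    response <- match.arg(response)
    mx <- if (response == "correct")
      .mixture_cdf(params, v, t, numeric(0), n_nodes, tol, kmax)$F_upper
    else
      .mixture_cdf(params, v, numeric(0), t, n_nodes, tol, kmax)$F_lower
    p_resp <- if (response == "correct") p_correct else 1 - p_correct
    (1 - po) * mx + po * p_resp * .contaminant_cdf(t, cont_window)
  }

  quantile_fun <- function(p, response = c("correct", "error")) {
    response <- match.arg(response)
    p_resp <- if (response == "correct") p_correct else 1 - p_correct
    vapply(p, function(pp) {
      stopifnot(pp > 0, pp < 1)
      target <- pp * p_resp
      stats::uniroot(function(t) cdf(t, response) - target,
                     lower = 1e-4, upper = 10, tol = 1e-7,
                     extendInt = "upX")$root
    }, 0)
  }

  bin_probs <- function(cuts_correct, cuts_error = cuts_correct) {
    pc <- c(cdf(cuts_correct, "correct"), p_correct)
    pe <- c(cdf(cuts_error, "error"), 1 - p_correct)
    list(correct = diff(c(0, pc)), error = diff(c(0, pe)))
  }

  structure(list(ratio = ratio, drift = v, p_correct = p_correct,
                 cdf = cdf, quantile = quantile_fun, bin_probs = bin_probs,
                 params = params, cont_window = cont_window,
                 n_nodes = n_nodes),
            class = "ddm_cond_pred")
}

#' @export
print.ddm_cond_pred <- function(x, digits = 4, ...) {
  cat(sprintf("Condition %s: drift %.4f, P(correct) %.4f\n",
              x$ratio, x$drift, x$p_correct))
  q <- x$quantile(c(0.1, 0.5, 0.9), "correct")
  cat("  correct RT quantiles (.1/.5/.9):",
      paste(round(q, digits), collapse = " / "), "s\n")
  invisible(x)
}
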