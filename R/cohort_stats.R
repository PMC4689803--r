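# Cohort-level analyses: split-half reliability with Spearman-Brown
# correction, Steiger's test for dependent correlations, regression of math
# score with covariates, inverse efficiency, trial-subset reliability
# curves, and the half-cohort resampling analysis.

#' Split-half reliability with Spearman-Brown correction
#'
#' Pearson correlation between estimates from two half-tests (e.g. even and
#' odd blocks), projected to full-test reliability by the Spearman-Brown
#' formula `2 r / (1 + r)`.
#'
#' @param estimates_even,estimates_odd Paired numeric vectors (length >= 3)
#'   of per-participant estimates from the two halves.
#' @return Corrected reliability; the raw half correlation is attached as
#'   attribute `half_r`. `NA` with a warning if either half has zero
#'   variance.
#' @examples
#' split_half_reliability(1:10, 1:10)          # 1
#' @export
split_half_reliability <- function(estimates_even, estimates_odd) {
  stopifnot(length(estimates_even) == length(estimates_odd),
            length(estimates_even) >= 3L)
  if (sd(estimates_even) == 0 || sd(estimates_odd) == 0) {
    warning("zero variance in one half; reliability undefined")
    return(structure(NA_real_, half_r = NA_real_))
  }
  r <- cor(estimates_even, estimates_odd)
  structure(2 * r / (1 + r), half_r = r)
}

#' Steiger's z test for two dependent correlations sharing one variable
#'
#' Tests whether `cor(x, y)` differs from `cor(x, z)` given the correlation
#' `cor(y, z)`, using Steiger's (1980) modified Fisher-z statistic for
#' dependent correlations with one variable in common.
#'
#' @param r_xy,r_xz The two correlations being compared (shared variable x).
#' @param r_yz Correlation between the two non-shared variables.
#' @param n Sample size (> 3).
#' @return An object of class `htest` with the z statistic and two-sided p.
#' @export
steiger_test <- function(r_xy, r_xz, r_yz, n) {
  stopifnot(n > 3, abs(r_xy) < 1, abs(r_xz) < 1, abs(r_yz) < 1)
  detR <- 1 + 2 * r_xy * r_xz * r_yz - r_xy^2 - r_xz^2 - r_yz^2
  if (detR < 0)
    stop("degenerate correlation matrix (not positive semi-definite)")
  z1 <- atanh(r_xy)
  z2 <- atanh(r_xz)
  rbar <- (r_xy + r_xz) / 2
  psi <- r_yz * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_yz^2)
  cc <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cc))
  p <- 2 * pnorm(-abs(z))
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz),
                 parameter = c(n = n),
                 method = "Steiger's z for dependent correlations (one variable in common)",
                 data.name = sprintf("r_xy = %.3f vs r_xz = %.3f", r_xy, r_xz),
                 alternative = "two.sided"),
            class = "htest")
}

#' Inverse efficiency score
#'
#' Mean RT divided by proportion correct: a heuristic composite of speed and
#' accuracy without a process interpretation.
#'
#' @param mean_rt Mean response time (s).
#' @param accuracy Proportion correct, > 0.
#' @return Inverse efficiency in seconds.
#' @export
inverse_efficiency <- function(mean_rt, accuracy) {
  if (any(accuracy <= 0)) stop("inverse efficiency undefined at accuracy 0")
  mean_rt / accuracy
}

#' Regression of math score on acuity estimates with covariates
#'
#' Ordinary least squares of the math score on the named predictor columns,
#' reporting per-coefficient t and two-sided p plus the model R-squared.
#' Used to test whether the drift scale predicts math over and above
#' `log_w` or the inverse efficiency score.
#'
#' @param table Per-participant data frame containing a `math` column and
#'   the predictor columns.
#' @param predictors Character vector of predictor column names.
#' @return List with `coefficients` (matrix with estimate, t, p),
#'   `r_squared`, `n`, and the underlying `lm` fit.
#' @export
regression_math <- function(table, predictors) {
  stopifnot("math" %in% names(table), all(predictors %in% names(table)))
  dat <- table[, c("math", predictors), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(predictors) + 2L)
    stop("need at least predictors + 2 complete cases")
  fml <- stats::as.formula(paste("math ~", paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit))))
    stop("rank-deficient design: collinear predictors")
  sm <- summary(fit)
  list(coefficients = sm$coefficients[, c("Estimate", "t value", "Pr(>|t|)"),
                                      drop = FALSE],
       r_squared = sm$r.squared, n = nrow(dat), fit = fit)
}

# Pearson p-value without cor.test overhead
.cor_p <- function(r, n) 2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2)

#' Reliability and math-correlation curves over trial subsets
#'
#' For each subset size, the first `k` trials (presentation order) of every
#' participant are used to (i) estimate the Weber fraction and drift scale
#' separately from even and odd blocks, giving a Spearman-Brown-corrected
#' split-half reliability per estimator, and (ii) estimate both from the
#' whole subset, giving the correlation of each estimator with the math
#' score.
#'
#' @param trials Validated cohort trial data frame.
#' @param math Named numeric vector of math scores (names = participant ids),
#'   or `NULL` to skip the math correlations.
#' @param sizes Subset sizes in trials (default the design's block multiples
#'   128, 256, 384, 512, 640, 768).
#' @param seed Base seed; participant `i` uses `seed + i` for every fit, so
#'   the full-length subset reproduces the full-data fit exactly.
#' @param ... Passed to [fit_ddm()] (e.g. `restarts`, `maxit`).
#' @return Data frame with one row per size: split-half reliabilities and
#'   (if `math` given) math correlations for `w` and `vs`. Sizes too small
#'   to fit are skipped with a warning.
#' @export
subset_reliability_curve <- function(trials, math = NULL,
                                     sizes = c(128L, 256L, 384L, 512L,
                                               640L, 768L),
                                     seed = 1L, ...) {
  ids <- unique(trials$participant_id)
  per <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    tr[order(tr$block, tr$trial), , drop = FALSE]
  })
  names(per) <- ids
  rows <- lapply(sizes, function(k) {
    est <- tryCatch({
      vals <- lapply(seq_along(per), function(i) {
        sub <- head(per[[i]], k)
        even <- sub[sub$block %% 2L == 0L, , drop = FALSE]
        odd <- sub[sub$block %% 2L == 1L, , drop = FALSE]
        fit_half <- function(dd, sd_off) {
          conds <- collapse_conditions(dd)
          c(w = fit_weber(conds)$w,
            vs = fit_ddm(conds, seed = seed + i + sd_off, ...)$params$vs)
        }
        c(full = fit_half(sub, 0L), even = fit_half(even, 10000L),
          odd = fit_half(odd, 20000L))
      })
      do.call(rbind, vals)
    }, error = function(e) {
      warning("subset size ", k, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(est)) return(NULL)
    out <- data.frame(
      size = k,
      reliability_w = as.numeric(split_half_reliability(est[, "even.w"],
                                                        est[, "odd.w"])),
      reliability_vs = as.numeric(split_half_reliability(est[, "even.vs"],
                                                         est[, "odd.vs"])),
      w_full = NA, vs_full = NA, r_math_w = NA, r_math_vs = NA)
    if (!is.null(math)) {
      m <- math[as.character(ids)]
      out$r_math_w <- cor(log(est[, "full.w"]), m)
      out$r_math_vs <- cor(est[, "full.vs"], m)
    }
    out$w_full <- mean(est[, "full.w"])
    out$vs_full <- mean(est[, "full.vs"])
    out
  })
  do.call(rbind, rows)
}

#' Half-cohort resampling analysis
#'
#' Repeatedly draws `subset_n` participants without replacement, screens for
#' subsamples in which the accuracy--RT correlation is non-significant
#' (`p > alpha`), and among those compares the magnitude of the drift
#' scale--math correlation with the `log(w)`--math correlation. Draw `r` is
#' seeded by `seed + r` on the sorted participant identifiers, so the result
#' is invariant to row order.
#'
#' @param table Per-participant data frame with columns `participant_id`,
#'   `accuracy`, `mean_rt`, `vs`, `log_w`, `math`.
#' @param reps Number of resampling repetitions (default 1e5).
#' @param subset_n Participants per draw (default 55).
#' @param alpha Screening level for the accuracy-RT correlation.
#' @param seed Base seed for the per-draw RNG.
#' @return List with `reps`, `n_nonsignificant` (draws passing the screen),
#'   `n_vs_greater` (screened draws with `|r(vs, math)| > |r(log_w, math)|`)
#'   and `fraction` (their ratio, `NaN` if no draw passes).
#' @export
half_cohort_resampling <- function(table, reps = 100000L, subset_n = 55L,
                                   alpha = 0.05, seed = 1L) {
  need <- c("participant_id", "accuracy", "mean_rt", "vs", "log_w", "math")
  stopifnot(all(need %in% names(table)))
  if (subset_n > nrow(table))
    stop("subset_n exceeds the cohort size")
  if (reps == 0L)
    return(list(reps = 0L, n_nonsignificant = 0L, n_vs_greater = 0L,
                fraction = NaN))
  tab <- table[order(as.character(table$participant_id)), , drop = FALSE]
  acc <- tab$accuracy; rt <- tab$mean_rt
  vs <- tab$vs; lw <- tab$log_w; math <- tab$math
  .with_seed(seed, {
    n_ns <- 0L; n_win <- 0L
    for (r in seq_len(reps)) {
      set.seed(seed + r)
      idx <- sample.int(nrow(tab), subset_n)
      rc <- cor(acc[idx], rt[idx])
      if (.cor_p(rc, subset_n) > alpha) {
        n_ns <- n_ns + 1L
        if (abs(cor(vs[idx], math[idx])) > abs(cor(lw[idx], math[idx])))
          n_win <- n_win + 1L
      }
    }
    list(reps = reps, n_nonsignificant = n_ns, n_vs_greater = n_win,
         fraction = if (n_ns > 0L) n_win / n_ns else NaN)
  })
}

#' Cohort-level analysis of fitted estimates
#'
#' Assembles the per-participant table (drift-scale and Weber estimates,
#' accuracy, mean RT, inverse efficiency, math score) and the headline
#' statistics: correlations of math with `vs` and `log_w`, Steiger's test of
#' their difference, and regressions of math on `vs` controlling for `log_w`
#' and for inverse efficiency.
#'
#' @param cohort_fit Result of [fit_ddm_cohort()] (with `weber = TRUE`).
#' @param math Named numeric vector of math scores (names = participant ids).
#' @return List with `table` (per-participant) and `stats` (named list of
#'   correlations with p-values, the Steiger `htest`, and the two
#'   [regression_math()] results).
#' @export
analyze_cohort <- function(cohort_fit, math) {
  tab <- cohort_fit$table
  stopifnot(all(c("vs", "log_w") %in% names(tab)))
  tab$math <- as.numeric(math[as.character(tab$participant_id)])
  tab$inverse_efficiency <- inverse_efficiency(tab$mean_rt, tab$accuracy)
  n <- nrow(tab)
  r_vs <- cor(tab$vs, tab$math)
  r_lw <- cor(tab$log_w, tab$math)
  r_third <- cor(tab$vs, tab$log_w)
  r_ies <- cor(tab$inverse_efficiency, tab$math)
  stats <- list(
    r_vs_math = c(r = r_vs, p = .cor_p(r_vs, n)),
    r_logw_math = c(r = r_lw, p = .cor_p(r_lw, n)),
    r_ies_math = c(r = r_ies, p = .cor_p(r_ies, n)),
    steiger = steiger_test(r_vs, -r_lw, -r_third, n),
    regression_logw = regression_math(tab, c("vs", "log_w")),
    regression_ies = regression_math(tab, c("vs", "inverse_efficiency"))
  )
  list(table = tab, stats = stats)
}
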