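test_that("split-half reliability applies the Spearman-Brown projection", {
  expect_equal(as.numeric(split_half_reliability(1:10, 1:10)), 1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  # rank-free textbook Pearson formula as the oracle
  r_oracle <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    ((length(x) - 1) * sd(x) * sd(y))
  out <- split_half_reliability(x, y)
  expect_equal(attr(out, "half_r"), r_oracle, tolerance = 1e-12)
  expect_equal(as.numeric(out), 2 * r_oracle / (1 + r_oracle))
  # closed form at r = 0.5
  expect_equal(2 * 0.5 / 1.5, 2 / 3)
  expect_warning(out <- split_half_reliability(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(out))
})

test_that("Steiger's z is zero under equality and grows with n", {
  eq <- steiger_test(0.4, 0.4, 0.3, 50)
  expect_equal(unname(eq$statistic), 0)
  expect_equal(eq$p.value, 1)
  z1 <- abs(steiger_test(0.5, 0.2, 0.3, 50)$statistic)
  z2 <- abs(steiger_test(0.5, 0.2, 0.3, 500)$statistic)
  z3 <- abs(steiger_test(0.5, 0.2, 0.3, 5000)$statistic)
  expect_true(z1 < z2 && z2 < z3)
  expect_error(steiger_test(0.9, -0.9, 0.9, 50), "positive semi-definite")
})

test_that("Steiger's z holds its nominal type-I rate on trivariate Gaussians", {
  # null: cor(x,y) = cor(x,z); Monte-Carlo calibration oracle
  Sigma <- matrix(c(1, 0.4, 0.4,
                    0.4, 1, 0.3,
                    0.4, 0.3, 1), 3, 3)
  L <- chol(Sigma)
  set.seed(401)
  n <- 60; reps <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    X <- matrix(rnorm(n * 3), n, 3) %*% L
    rej[i] <- steiger_test(cor(X[, 1], X[, 2]), cor(X[, 1], X[, 3]),
                           cor(X[, 2], X[, 3]), n)$p.value < 0.05
  }
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.075)
})

test_that("inverse efficiency behaves as RT over accuracy", {
  expect_equal(inverse_efficiency(0.5, 1.0), 0.5)
  expect_equal(inverse_efficiency(0.5, 0.5), 1.0)
  expect_gt(inverse_efficiency(0.6, 0.7), inverse_efficiency(0.6, 0.9))
  expect_error(inverse_efficiency(0.5, 0), "undefined")
})

test_that("regression of math on acuity estimates is calibrated and powered", {
  set.seed(402)
  n <- 80
  # null: math is pure noise -> vs coefficient significant at the nominal rate
  rej <- vapply(1:150, function(i) {
    tab <- data.frame(vs = rnorm(n), log_w = rnorm(n), math = rnorm(n))
    regression_math(tab, c("vs", "log_w"))$coefficients["vs", 3] < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.12)
  # signal: math linear in vs at rho ~ 0.45 -> majority significant
  hit <- vapply(1:60, function(i) {
    vs <- rnorm(n)
    tab <- data.frame(vs = vs, log_w = -0.4 * vs + rnorm(n, 0, 1),
                      math = 0.5 * vs + rnorm(n, 0, 1))
    regression_math(tab, c("vs", "log_w"))$coefficients["vs", 3] < 0.05
  }, TRUE)
  expect_gt(mean(hit), 0.5)
  tab <- data.frame(vs = rnorm(20), math = rnorm(20))
  tab$vs2 <- tab$vs
  expect_error(regression_math(tab, c("vs", "vs2")), "collinear")
})

test_that("half-cohort resampling screens and compares correlations", {
  set.seed(403)
  n <- 110
  vs <- rnorm(n)
  tab <- data.frame(participant_id = sprintf("p%03d", 1:n),
                    accuracy = rnorm(n), mean_rt = rnorm(n),
                    vs = vs, log_w = rnorm(n), math = vs)
  res <- half_cohort_resampling(tab, reps = 300, subset_n = 55, seed = 9)
  # math is a deterministic function of vs: vs wins every screened draw
  expect_gt(res$n_nonsignificant, 0)
  expect_equal(res$fraction, 1)
  # vacuous call
  res0 <- half_cohort_resampling(tab, reps = 0)
  expect_equal(res0$n_nonsignificant, 0L)
  expect_true(is.nan(res0$fraction))
  expect_error(half_cohort_resampling(tab, reps = 10, subset_n = 200),
               "exceeds")
})

test_that("resampling summaries are invariant to participant row order", {
  set.seed(404)
  n <- 80
  tab <- data.frame(participant_id = sprintf("p%03d", 1:n),
                    accuracy = rnorm(n), mean_rt = rnorm(n),
                    vs = rnorm(n), log_w = rnorm(n), math = rnorm(n))
  r1 <- half_cohort_resampling(tab, reps = 200, subset_n = 40, seed = 5)
  perm <- tab[sample.int(n), , drop = FALSE]
  r2 <- half_cohort_resampling(perm, reps = 200, subset_n = 40, seed = 5)
  expect_identical(r1, r2)
})

test_that("subset curves reproduce full-data fits at the identity subset", {
  cohort <- cached("subset_cohort",
                   generate_cohort(cohort_spec(3, blocks = 4), seed = 405))
  trials <- validate_trials(cohort$trials)
  math <- setNames(cohort$truth$math, cohort$truth$participant_id)
  # at-ceiling halves of small subsets legitimately pin w to its bound
  curve <- suppressWarnings(
    subset_reliability_curve(trials, math, sizes = c(128L, 256L),
                             seed = 50, restarts = 1, maxit = 60))
  expect_equal(nrow(curve), 2L)
  expect_true(all(is.finite(curve$reliability_w)))
  # identity subset: the full-subset estimates at the full trial count equal
  # direct fits with the same seeds
  ids <- unique(trials$participant_id)
  direct <- vapply(seq_along(ids), function(i) {
    tr <- trials[trials$participant_id == ids[i], , drop = FALSE]
    fit_ddm(collapse_conditions(tr), seed = 50 + i, restarts = 1,
            maxit = 60)$params$vs
  }, 0)
  expect_equal(curve$vs_full[curve$size == 256L], mean(direct),
               tolerance = 1e-12)
  # infeasibly small subsets are skipped with a warning (an 8-trial subset
  # also legitimately warns about pinned w before the fit fails)
  expect_warning(
    expect_warning(
      small <- subset_reliability_curve(trials, math, sizes = 8L,
                                        seed = 50, restarts = 1, maxit = 40),
      "skipped"),
    "pinned")
  expect_null(small)
})
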