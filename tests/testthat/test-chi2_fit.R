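# helper: bins built from fixed synthetic RTs so collapse rules are exact
.bins_from_counts <- function(nc, ne) build_bins(make_conditions(nc, ne))

test_that("bin building follows the quantile / median / count collapse rules", {
  conds <- make_conditions(c(100L, 9L, 5L, 1L), c(5L, 2L, 1L, 0L))
  bins <- build_bins(conds)
  b1 <- bins$conditions[[1]]
  expect_equal(b1$correct$level, "quantile")
  expect_equal(b1$correct$freq, c(10, 20, 20, 20, 20, 10))
  expect_equal(length(b1$correct$cuts), 5L)
  expect_equal(b1$error$level, "median")
  expect_equal(sum(b1$error$freq), 5L)
  expect_true(all(sort(b1$error$freq) == c(2, 3)))
  b2 <- bins$conditions[[2]]
  expect_equal(b2$correct$level, "quantile") # 9 responses: full quantile set
  expect_equal(b2$error$level, "median")    # 2 responses
  expect_equal(b2$error$freq, c(1, 1))
  b3 <- bins$conditions[[3]]
  expect_equal(b3$correct$level, "median")  # 5 responses
  expect_equal(b3$error$level, "count")     # 1 response: no RT information
  expect_equal(b3$error$freq, 1L)
  b4 <- bins$conditions[[4]]
  expect_equal(b4$correct$level, "count")
  expect_equal(b4$error$freq, 0L)
})

test_that("degrees of freedom follow the frequencies-minus-constraints rule", {
  full <- .bins_from_counts(rep(100L, 4), rep(20L, 4))
  expect_equal(degrees_of_freedom(full), 44L)
  # each fully-populated condition: 12 frequencies, 11 df
  one <- build_bins(make_conditions(c(100L, 100L, 100L, 100L),
                                    c(20L, 20L, 20L, 20L))$`4:3`)
  expect_equal(degrees_of_freedom(one), 11L)
  # a condition collapsed to 6 + 2 bins contributes 7
  mixed <- .bins_from_counts(c(100L, 100L, 100L, 100L), c(5L, 20L, 20L, 20L))
  expect_equal(degrees_of_freedom(mixed), 44L - 11L + 7L)
  # all conditions count-only on both responses: 1 df each
  tiny <- .bins_from_counts(rep(1L, 4), rep(1L, 4))
  expect_equal(degrees_of_freedom(tiny), 4L)
})

test_that("chi-square objective is near zero at a self-consistent fit and
           grows under perturbation", {
  p <- typical_params()
  # synthesise observed frequencies from the model's own bin probabilities
  cuts <- c(0.45, 0.52, 0.58, 0.68, 0.85)
  n_cond <- 1000L
  conds <- lapply(ans_ratio_levels(), function(r) {
    pred <- predict_condition(p, r, cont_window = c(0.3, 1.5))
    bp <- pred$bin_probs(cuts)
    list(correct = n_cond * bp$correct, error = n_cond * bp$error)
  })
  names(conds) <- ans_ratio_levels()
  # build an ans_bins skeleton with those expectations as observations
  skel <- make_conditions(rep(30L, 4), rep(30L, 4))
  bins <- build_bins(skel)
  for (r in ans_ratio_levels()) {
    bins$conditions[[r]]$n <- n_cond
    bins$conditions[[r]]$window <- c(0.3, 1.5)
    bins$conditions[[r]]$correct <- list(level = "quantile", cuts = cuts,
                                         freq = conds[[r]]$correct,
                                         n = sum(conds[[r]]$correct))
    bins$conditions[[r]]$error <- list(level = "quantile", cuts = cuts,
                                       freq = conds[[r]]$error,
                                       n = sum(conds[[r]]$error))
  }
  chi0 <- chi2_objective(p, bins, cont_window = c(0.3, 1.5))
  expect_lt(chi0, 1e-10)
  # moving k observations between bins strictly increases the objective
  pert <- bins
  pert$conditions[[1]]$correct$freq[1] <-
    pert$conditions[[1]]$correct$freq[1] + 5
  pert$conditions[[1]]$correct$freq[3] <-
    pert$conditions[[1]]$correct$freq[3] - 5
  expect_gt(chi2_objective(p, pert, cont_window = c(0.3, 1.5)), chi0 + 0.1)
})

test_that("objective prefers the generating parameters over a distorted set", {
  p <- typical_params()
  tr <- cached("big_participant", {
    design <- ans_design(blocks = 10L, trials_per_block = 1024L)
    simulate_participant(p, design, seed = 77)
  })
  bins <- build_bins(collapse_conditions(validate_trials(tr)))
  p_wrong <- typical_params(vs = 2 * p$vs)
  expect_lt(chi2_objective(p, bins), chi2_objective(p_wrong, bins))
})

test_that("fits are deterministic given a seed", {
  tr <- validate_trials(simulate_participant(typical_params(), seed = 9))
  conds <- collapse_conditions(tr)
  f1 <- fit_ddm(conds, restarts = 1, maxit = 60, seed = 4)
  f2 <- fit_ddm(conds, restarts = 1, maxit = 60, seed = 4)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$chi2, f2$chi2)
})

test_that("shifting all RTs moves non-decision time, not the drift scale", {
  tr <- validate_trials(simulate_participant(typical_params(), seed = 13))
  shifted <- tr
  shifted$rt <- tr$rt + 0.2
  f0 <- fit_ddm(collapse_conditions(tr), restarts = 3, maxit = 500, seed = 6)
  f1 <- fit_ddm(collapse_conditions(shifted), restarts = 3, maxit = 500,
                seed = 6)
  expect_equal(f1$params$ter - f0$params$ter, 0.2, tolerance = 0.05)
  expect_lt(abs(f1$params$vs - f0$params$vs), 0.25)
  expect_lt(abs(f1$params$a - f0$params$a), 0.02)
})

test_that("a more cautious synthetic participant yields a larger boundary,
           similar drift scale", {
  p_lo <- typical_params()
  p_hi <- typical_params(a = p_lo$a * 1.5)
  f_lo <- fit_ddm(collapse_conditions(
    validate_trials(simulate_participant(p_lo, seed = 31))),
    restarts = 2, maxit = 300, seed = 8)
  f_hi <- fit_ddm(collapse_conditions(
    validate_trials(simulate_participant(p_hi, seed = 32))),
    restarts = 2, maxit = 300, seed = 8)
  expect_gt(f_hi$params$a, f_lo$params$a + 0.02)
  expect_lt(abs(f_hi$params$vs - f_lo$params$vs), 0.35)
})

test_that("fit results carry coherent structure and methods", {
  tr <- validate_trials(simulate_participant(typical_params(), seed = 9))
  fit <- cached("fit9", fit_ddm(collapse_conditions(tr), restarts = 2,
                                maxit = 300, seed = 2))
  expect_s3_class(fit, "ddm_fit")
  expect_equal(fit$df, degrees_of_freedom(fit$bins))
  expect_gte(fit$chi2, 0)
  expect_named(coef(fit), c("a", "sz", "vs", "eta", "ter", "st", "po"))
  expect_output(print(fit), "chi-square")
  preds <- predict(fit)
  expect_length(preds, 4L)
  expect_true(all(vapply(preds, `[[`, 0, "p_correct") > 0.5))
  sim <- simulate(fit, seed = 1)
  expect_equal(nrow(sim), 768L)
})
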