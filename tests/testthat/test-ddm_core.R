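test_that("drift rate scales the log ratio and checks its domain", {
  expect_equal(drift_rate(1, 4, 3), log(4) - log(3))
  expect_equal(drift_rate(0, 4, 3), 0)
  expect_equal(drift_rate(2, 20, 15), 2 * (log(4) - log(3)))
  expect_error(drift_rate(1, 9, 12), "n_l must exceed")
})

test_that("absorption probability: symmetry, limits, and simulation oracle", {
  a <- 0.093
  expect_equal(absorption_prob(0, a), 0.5)
  expect_equal(absorption_prob(1e-12, a), 0.5, tolerance = 1e-6)
  expect_equal(absorption_prob(50, a), 1, tolerance = 1e-9)
  expect_equal(absorption_prob(-50, a), 0, tolerance = 1e-9)
  expect_error(absorption_prob(0.3, a, z = a), "strictly in")
  # independent oracle: Euler-Maruyama simulation of the bare process
  set.seed(101)
  sim <- ansacuity:::cpp_simulate_ddm(100000L, 0.33, 0, a, 0, 0, 0, 0, 0.1,
                                      1e-4, 0.2, 3, 10, TRUE)
  p_hat <- mean(sim$response)
  se <- sqrt(p_hat * (1 - p_hat) / 1e5)
  expect_lt(abs(absorption_prob(0.33, a) - p_hat), 3 * se)
})

test_that("first-passage CDF: boundary values and conservation", {
  a <- 0.093; v <- 0.2
  expect_equal(fpt_cdf(0, "correct", v, a), 0)
  expect_equal(fpt_cdf(0, "error", v, a), 0)
  total <- fpt_cdf(50, "correct", v, a) + fpt_cdf(50, "error", v, a)
  expect_equal(total, 1, tolerance = 1e-7)
  expect_equal(fpt_cdf(50, "correct", v, a), absorption_prob(v, a),
               tolerance = 1e-7)
  # nondecreasing defective CDF
  tt <- seq(0, 2, by = 0.01)
  expect_true(all(diff(fpt_cdf(tt, "correct", v, a)) >= 0))
})

test_that("first-passage CDF matches simulated passages within the DKW band", {
  a <- 0.093; v <- 0.18; s <- 0.1
  set.seed(202)
  n <- 100000L
  sim <- ansacuity:::cpp_simulate_ddm(n, v, 0, a, 0, 0, 0, 0, s,
                                      1e-4, 0.2, 3, 10, TRUE)
  for (resp in c(1L, 0L)) {
    dts <- sort(sim$rt[sim$response == resp])
    m <- length(dts)
    lab <- if (resp == 1L) "correct" else "error"
    p_resp <- if (resp == 1L) absorption_prob(v, a, s = s)
              else 1 - absorption_prob(v, a, s = s)
    Fm <- fpt_cdf(dts, lab, v, a, s = s) / p_resp
    emp_hi <- seq_len(m) / m
    emp_lo <- (seq_len(m) - 1) / m
    sup_d <- max(pmax(abs(Fm - emp_hi), abs(Fm - emp_lo)))
    dkw99 <- sqrt(log(2 / 0.01) / (2 * m))
    expect_lt(sup_d, dkw99)
  }
})

test_that("degenerate mixture reduces to the bare process", {
  p <- ddm_params(a = 0.1, sz = 0, vs = 1.2, eta = 0, ter = 0.4, st = 0,
                  po = 0)
  pred <- predict_condition(p, "7:6")
  v <- 1.2 * (log(7) - log(6))
  expect_equal(pred$p_correct, absorption_prob(v, 0.1), tolerance = 1e-9)
  tt <- c(0.5, 0.7, 1.0)
  expect_equal(pred$cdf(tt, "correct"),
               fpt_cdf(tt - 0.4, "correct", v, 0.1), tolerance = 1e-9)
})

test_that("predictions conserve probability and respond monotonically", {
  p0 <- typical_params()
  for (r in c("4:3", "10:9")) {
    pred <- predict_condition(p0, r)
    bp <- pred$bin_probs(c(0.45, 0.55, 0.65, 0.8, 1.1))
    expect_equal(sum(bp$correct) + sum(bp$error), 1, tolerance = 1e-6)
    expect_true(all(bp$correct >= 0 & bp$error >= 0))
  }
  # easier ratios are more accurate
  expect_gt(predict_condition(p0, "4:3")$p_correct,
            predict_condition(p0, "10:9")$p_correct)
  # p_correct nondecreasing in a and vs; median correct RT nondecreasing in a
  accs_a <- rts_a <- numeric(0)
  for (a in c(0.07, 0.093, 0.13)) {
    pr <- predict_condition(ddm_params(a = a, sz = 0.02), "7:6")
    accs_a <- c(accs_a, pr$p_correct)
    rts_a <- c(rts_a, pr$quantile(0.5, "correct"))
  }
  expect_true(all(diff(accs_a) > 0))
  expect_true(all(diff(rts_a) > 0))
  accs_v <- vapply(c(0.6, 1.16, 1.8), function(vs)
    predict_condition(ddm_params(vs = vs), "7:6")$p_correct, 0)
  expect_true(all(diff(accs_v) > 0))
})

test_that("the diffusion coefficient is only a gauge", {
  # scaling a, z, sz, drift and s by a common factor leaves predictions fixed
  k <- 2.5
  p1 <- ddm_params(a = 0.093, sz = 0.023, vs = 1.163, eta = 0.167,
                   ter = 0.414, st = 0.219, po = 0.01, s = 0.1)
  p2 <- ddm_params(a = 0.093 * k, sz = 0.023 * k, vs = 1.163 * k,
                   eta = 0.167 * k, ter = 0.414, st = 0.219, po = 0.01,
                   s = 0.1 * k)
  for (r in c("4:3", "9:8")) {
    pr1 <- predict_condition(p1, r)
    pr2 <- predict_condition(p2, r)
    expect_equal(pr1$p_correct, pr2$p_correct, tolerance = 1e-9)
    tt <- c(0.5, 0.8)
    expect_equal(pr1$cdf(tt, "correct"), pr2$cdf(tt, "correct"),
                 tolerance = 1e-8)
  }
})

test_that("doubling quadrature nodes leaves bin probabilities unchanged", {
  p <- typical_params()
  cuts <- c(0.45, 0.55, 0.65, 0.8, 1.1)
  for (r in c("4:3", "10:9")) {
    b1 <- predict_condition(p, r)$bin_probs(cuts)
    b2 <- predict_condition(p, r, n_nodes = 26L)$bin_probs(cuts)
    expect_lt(max(abs(c(b1$correct - b2$correct,
                        b1$error - b2$error))), 1e-5)
  }
})
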