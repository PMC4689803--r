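# Trial-level generative model of the study: balanced 12-block design,
# Euler-Maruyama sampling of the diffusion process (with a Brownian-bridge
# crossing test per step), cohort heterogeneity around typical adult
# parameter values, math scores correlated with drift scale, and the
# alternative linear-scale/scalar-variability generator used as a contrast
# in the RT diagnostic.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Balanced trial design for the comparison task
#'
#' Builds the within-participant design: `blocks` blocks of
#' `trials_per_block` trials, fully crossing the four ratios, the side of the
#' larger array, and the two stimulus-control flags (total-surface-area vs
#' item-area equated; density vs convex-field equated), with trial order
#' shuffled within block. Numerosity pairs are drawn uniformly from the
#' admissible integer pairs with both counts in 9--21 for each ratio.
#'
#' @param blocks Number of blocks (default 12).
#' @param trials_per_block Trials per block; must be a multiple of 32
#'   (4 ratios x 2 sides x 2 x 2 control flags), default 64.
#' @return Data frame with columns `block`, `trial`, `n_left`, `n_right`,
#'   `area_control`, `field_control`, `ratio`.
#' @export
ans_design <- function(blocks = 12L, trials_per_block = 64L) {
  if (trials_per_block %% 32L != 0L)
    stop("trials_per_block must be a multiple of 32 for a balanced design")
  cells <- expand.grid(ratio = ans_ratio_levels(),
                       larger_left = c(TRUE, FALSE),
                       area_control = c(0L, 1L), field_control = c(0L, 1L),
                       stringsAsFactors = FALSE)
  reps <- trials_per_block %/% 32L
  out <- lapply(seq_len(blocks), function(b) {
    blk <- cells[rep(seq_len(nrow(cells)), reps), , drop = FALSE]
    blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
    pair <- lapply(blk$ratio, function(r) {
      ps <- .ans_pairs[[r]]
      ps[[sample.int(length(ps), 1L)]]
    })
    nl <- vapply(pair, `[`, 0L, 1L)
    ns <- vapply(pair, `[`, 0L, 2L)
    data.frame(block = b, trial = seq_len(nrow(blk)),
               n_left = ifelse(blk$larger_left, nl, ns),
               n_right = ifelse(blk$larger_left, ns, nl),
               area_control = blk$area_control,
               field_control = blk$field_control,
               ratio = blk$ratio)
  })
  do.call(rbind, out)
}

#' Simulate a single diffusion-model trial
#'
#' Samples one trial: trial drift from `Normal(drift, eta)`, starting point
#' from `Uniform(a/2 - sz/2, a/2 + sz/2)`, Euler-Maruyama integration with a
#' Brownian-bridge boundary-crossing test each step, non-decision time from
#' `Uniform(ter - st/2, ter + st/2)`, and with probability `po` the RT is
#' replaced by a uniform contaminant draw (the response is kept).
#'
#' @param params A [ddm_params()] object.
#' @param drift Mean drift toward the correct boundary.
#' @param dt Integration step in seconds (default 1e-4).
#' @param cont_window Contaminant RT window.
#' @param horizon Maximum simulated decision time before resampling (s).
#' @param bridge Apply the bridge crossing correction (default `TRUE`).
#' @return List with `response` (`"correct"` or `"error"`) and `rt` seconds.
#' @export
simulate_trial <- function(params, drift, dt = 1e-4, cont_window = c(0.2, 3),
                           horizon = 10, bridge = TRUE) {
  stopifnot(inherits(params, "ddm_params"))
  sim <- cpp_simulate_ddm(1L, drift, params$eta, params$a, params$sz,
                          params$ter, params$st, params$po, params$s,
                          dt, cont_window[1], cont_window[2], horizon, bridge)
  list(response = if (sim$response[1] == 1L) "correct" else "error",
       rt = sim$rt[1])
}

#' Simulate one participant's full session
#'
#' Generates a balanced design (or uses the one supplied) and simulates every
#' trial from the diffusion process. Trials whose RT exceeds the `max_rt`
#' response window are recorded as omitted (empty response); their count is
#' attached as attribute `n_truncated`.
#'
#' @param params A [ddm_params()] object.
#' @param design Optional design data frame from [ans_design()].
#' @param dt Integration step (s).
#' @param cont_window Contaminant RT window.
#' @param participant_id Identifier written into the table.
#' @param seed Optional seed (caller's RNG state preserved).
#' @param max_rt Response window (s).
#' @param bridge Bridge crossing correction flag.
#' @return Trial data frame in the canonical study format.
#' @export
simulate_participant <- function(params, design = NULL, dt = 1e-4,
                                 cont_window = c(0.2, 3),
                                 participant_id = "p1", seed = NULL,
                                 max_rt = 3.0, bridge = TRUE) {
  stopifnot(inherits(params, "ddm_params"))
  .with_seed(seed, {
    if (is.null(design)) design <- ans_design()
    n <- nrow(design)
    correct <- logical(n)
    rt <- numeric(n)
    for (r in unique(design$ratio)) {
      idx <- which(design$ratio == r)
      v <- params$vs * .ans_log_ratio(r)
      sim <- cpp_simulate_ddm(length(idx), v, params$eta, params$a,
                              params$sz, params$ter, params$st, params$po,
                              params$s, dt, cont_window[1], cont_window[2],
                              10, bridge)
      correct[idx] <- sim$response == 1L
      rt[idx] <- sim$rt
    }
    larger_left <- design$n_left > design$n_right
    response <- ifelse(correct == larger_left, "left", "right")
    truncated <- rt > max_rt
    response[truncated] <- ""
    out <- data.frame(participant_id = participant_id,
                      block = design$block, trial = design$trial,
                      n_left = design$n_left, n_right = design$n_right,
                      response = response, rt = round(rt, 6),
                      area_control = design$area_control,
                      field_control = design$field_control)
    attr(out, "n_truncated") <- sum(truncated)
    out
  })
}

#' Cohort specification for the study simulator
#'
#' Describes a simulated cohort: participant-level diffusion parameters are
#' drawn as independent Gaussians truncated to the validity region
#' (resampled on violation), centred on typical young-adult values for this
#' task; math scores follow a latent linear model in the drift scale with
#' target correlation `rho_math`.
#'
#' @param n_participants Cohort size.
#' @param means,sds Named numeric vectors over
#'   `c("a","sz","vs","eta","ter","st","po")` giving the participant-level
#'   parameter distributions.
#' @param cov Optional 7x7 covariance matrix overriding `sds` for
#'   sensitivity studies (order as in `means`).
#' @param rho_math Target correlation between true drift scale and math
#'   score, `|rho_math| < 1` (default 0.3).
#' @param math_mean,math_sd Location and scale of the integer math score
#'   (problems solved in a timed arithmetic block); scores are rounded and
#'   floored at 0.
#' @param blocks,trials_per_block Design size (default 12 x 64 = 768).
#' @param dt Euler-Maruyama step (s).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants,
                        means = c(a = 0.093, sz = 0.023, vs = 1.163,
                                  eta = 0.167, ter = 0.414, st = 0.219,
                                  po = 0.004),
                        sds = c(a = 0.023, sz = 0.018, vs = 0.471,
                                eta = 0.110, ter = 0.081, st = 0.109,
                                po = 0.010),
                        cov = NULL, rho_math = 0.3, math_mean = 25,
                        math_sd = 8, blocks = 12L, trials_per_block = 64L,
                        dt = 1e-4) {
  pn <- c("a", "sz", "vs", "eta", "ter", "st", "po")
  stopifnot(all(pn %in% names(means)), all(pn %in% names(sds)))
  if (abs(rho_math) >= 1)
    stop("infeasible math-score correlation: |rho_math| must be < 1")
  if (!is.null(cov))
    stopifnot(is.matrix(cov), all(dim(cov) == 7L))
  structure(list(n_participants = as.integer(n_participants),
                 means = means[pn], sds = sds[pn], cov = cov,
                 rho_math = rho_math, math_mean = math_mean,
                 math_sd = math_sd, blocks = as.integer(blocks),
                 trials_per_block = as.integer(trials_per_block), dt = dt),
            class = "cohort_spec")
}

# draw one valid participant parameter set (truncation by rejection)
.draw_params <- function(spec) {
  L <- if (!is.null(spec$cov)) chol(spec$cov) else NULL
  for (i in 1:10000) {
    x <- if (is.null(L)) rnorm(7, spec$means, spec$sds)
         else spec$means + drop(rnorm(7) %*% L)
    p <- tryCatch(ddm_params(a = x[1], sz = x[2], vs = x[3], eta = x[4],
                             ter = x[5], st = x[6], po = x[7]),
                  error = function(e) NULL)
    if (!is.null(p) && p$vs > 0) return(p)
  }
  stop("could not draw a valid parameter set; check the cohort spec")
}

#' Generate a synthetic cohort
#'
#' Draws participant-level parameters and math scores from `spec`, simulates
#' every participant's session, and returns both the trial table (study
#' format) and the generating truth for recovery testing. Fully reproducible
#' under `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (caller's RNG state preserved).
#' @return List with `trials` (all participants' trials) and `truth`
#'   (per-participant generating parameters and `math` score).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(3), seed = 7)
#' table(cohort$trials$participant_id)
#' }
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(seed, {
    n <- spec$n_participants
    ids <- sprintf("p%03d", seq_len(n))
    plist <- lapply(seq_len(n), function(i) .draw_params(spec))
    vs <- vapply(plist, `[[`, 0, "vs")
    zvs <- (vs - spec$means["vs"]) / spec$sds["vs"]
    latent <- spec$rho_math * zvs +
      sqrt(1 - spec$rho_math^2) * rnorm(n)
    math <- pmax(0, round(spec$math_mean + spec$math_sd * latent))
    trials <- lapply(seq_len(n), function(i) {
      design <- ans_design(spec$blocks, spec$trials_per_block)
      simulate_participant(plist[[i]], design, dt = spec$dt,
                           participant_id = ids[i])
    })
    truth <- data.frame(participant_id = ids,
                        do.call(rbind, lapply(plist, as.double)),
                        math = as.numeric(math))
    list(trials = do.call(rbind, trials), truth = truth)
  })
}

#' Generate a cohort under the linear-scale/scalar-variability model
#'
#' Contrast generator for the model-comparison RT diagnostic: the mean drift
#' rate is held constant across ratio conditions while the across-trial
#' drift variability grows with the total number of items
#' (`eta = variability_slope * (n_left + n_right)`), so accuracy falls for
#' larger displays. Under this process, conditions with lower accuracy
#' produce *faster* mean RTs -- the signature that distinguishes it from the
#' log-scale fixed-variability model, for which lower-accuracy conditions
#' are slower.
#'
#' @param spec A [cohort_spec()]; its `means` supply `a`, `ter`, `st`, `sz`,
#'   `po` for every participant (no heterogeneity is needed for the
#'   diagnostic).
#' @param drift Constant mean drift toward the correct boundary (default
#'   0.25; together with the default slope this places the matched pairs in
#'   the 0.68--0.83 accuracy band typical of the task).
#' @param variability_slope Increase of `eta` per item of total numerosity
#'   (default 0.012).
#' @param seed Integer seed.
#' @return Trial data frame in the study format.
#' @export
generate_linear_scalar_cohort <- function(spec, drift = 0.25,
                                          variability_slope = 0.012,
                                          seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(seed, {
    m <- spec$means
    out <- lapply(seq_len(spec$n_participants), function(i) {
      design <- ans_design(spec$blocks, spec$trials_per_block)
      total <- design$n_left + design$n_right
      correct <- logical(nrow(design))
      rt <- numeric(nrow(design))
      for (tt in unique(total)) {
        idx <- which(total == tt)
        p <- ddm_params(a = m["a"], sz = m["sz"], vs = 1,
                        eta = variability_slope * tt, ter = m["ter"],
                        st = m["st"], po = m["po"])
        sim <- cpp_simulate_ddm(length(idx), drift, p$eta, p$a, p$sz,
                                p$ter, p$st, p$po, p$s, spec$dt, 0.2, 3,
                                10, TRUE)
        correct[idx] <- sim$response == 1L
        rt[idx] <- sim$rt
      }
      larger_left <- design$n_left > design$n_right
      response <- ifelse(correct == larger_left, "left", "right")
      response[rt > 3] <- ""
      data.frame(participant_id = sprintf("p%03d", i),
                 block = design$block, trial = design$trial,
                 n_left = design$n_left, n_right = design$n_right,
                 response = response, rt = round(rt, 6),
                 area_control = design$area_control,
                 field_control = design$field_control)
    })
    do.call(rbind, out)
  })
}
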