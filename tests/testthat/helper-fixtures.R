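# Shared fixtures: all test data are generated in code.

# typical young-adult generating parameters used across tests
typical_params <- function(...) ddm_params(...)

# a minimal hand-written trial table (two ratio conditions, one participant)
toy_trials <- function() {
  data.frame(
    participant_id = "s1", block = 1L, trial = 1:4,
    n_left = c(12L, 9L, 10L, 20L), n_right = c(9L, 12L, 9L, 18L),
    response = c("left", "left", "right", "left"),
    rt = c(0.52, 0.61, 0.70, 0.55),
    area_control = c(0L, 1L, 0L, 1L), field_control = c(0L, 0L, 1L, 1L)
  )
}

# build an ans_conditions object directly from counts (RTs synthesised as an
# increasing grid so binning is deterministic)
make_conditions <- function(n_correct, n_error,
                            rt_correct = NULL, rt_error = NULL) {
  ratios <- ans_ratio_levels()
  out <- lapply(seq_along(ratios), function(i) {
    rs <- as.integer(strsplit(ratios[i], ":")[[1]])
    cr <- if (is.null(rt_correct)) seq(0.4, 1.2, length.out = n_correct[i])
          else rt_correct[[i]]
    er <- if (is.null(rt_error)) {
      if (n_error[i] > 0) seq(0.45, 1.3, length.out = n_error[i])
      else numeric(0)
    } else rt_error[[i]]
    structure(list(ratio = ratios[i], n_l = rs[1], n_s = rs[2],
                   log_ratio = log(rs[1]) - log(rs[2]),
                   correct_rts = cr, error_rts = er,
                   n_correct = n_correct[i], n_error = n_error[i],
                   rt_min = suppressWarnings(min(c(cr, er), na.rm = TRUE)),
                   rt_max = suppressWarnings(max(c(cr, er), na.rm = TRUE))),
              class = "ans_condition")
  })
  names(out) <- ratios
  structure(out, class = "ans_conditions",
            n_trials = sum(n_correct) + sum(n_error), participant_id = "syn")
}

# session-level cache so expensive simulated cohorts are built once per file
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}
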