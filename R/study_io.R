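# Trial-level data model: reading/writing, validation, collapsing into ratio
# conditions, and participant exclusion rules.

.trial_columns <- c("participant_id", "block", "trial", "n_left", "n_right",
                    "response", "rt", "area_control", "field_control")

# exact integer ratio membership: max/min must equal one of the design ratios
.match_ratio <- function(n_left, n_right) {
  nl <- pmax(n_left, n_right)
  ns <- pmin(n_left, n_right)
  out <- rep(NA_character_, length(nl))
  for (r in names(.ans_ratios)) {
    rs <- .ans_ratios[[r]]
    out[nl * rs[2] == ns * rs[1]] <- r
  }
  out
}

#' Read trial-level comparison data
#'
#' Reads a delimited text file of numerosity-comparison trials and validates
#' every row against the study design: dot counts in 9--21 differing by one of
#' the four design ratios (4:3, 7:6, 9:8, 10:9 by exact integer comparison),
#' response `"left"` or `"right"`, and response time in (0, 3] seconds.
#' Rows with an empty response (omitted trials) are dropped with a message
#' reporting the count. RTs are in seconds throughout; files recorded in
#' milliseconds must be declared via `rt_unit = "ms"`.
#'
#' @param path Path to a delimited text file with a header row naming at least
#'   the columns `participant_id`, `block`, `trial`, `n_left`, `n_right`,
#'   `response`, `rt`, `area_control`, `field_control`.
#' @param sep Field separator (default comma).
#' @param rt_unit `"s"` (default) or `"ms"`; millisecond RTs are converted.
#' @param max_rt Response window in seconds; rows with `rt > max_rt` are
#'   rejected at parse time (default 3, the task's response deadline).
#' @return A `data.frame` of validated trials, one row per trial, with an
#'   added `ratio` factor column.
#' @seealso [write_trials()], [collapse_conditions()], [apply_exclusions()]
#' @export
read_trials <- function(path, sep = ",", rt_unit = c("s", "ms"), max_rt = 3.0) {
  rt_unit <- match.arg(rt_unit)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_columns, names(raw))
  if (length(missing))
    stop("trial file is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (rt_unit == "ms") raw$rt <- raw$rt / 1000
  validate_trials(raw, max_rt = max_rt)
}

#' Validate a data frame of trials
#'
#' Applies the same row-level checks as [read_trials()] to an in-memory data
#' frame. Malformed rows are reported with their row numbers.
#'
#' @param trials Data frame with the trial columns (see [read_trials()]).
#' @param max_rt Response window in seconds.
#' @return The validated data frame with a `ratio` column added; omitted
#'   (empty-response) rows dropped with a message.
#' @export
validate_trials <- function(trials, max_rt = 3.0) {
  missing <- setdiff(.trial_columns, names(trials))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  trials <- as.data.frame(trials)
  omitted <- is.na(trials$response) | trials$response == ""
  if (any(omitted)) {
    message(sum(omitted), " omitted (no-response) trial(s) dropped")
    trials <- trials[!omitted, , drop = FALSE]
  }
  row_id <- seq_len(nrow(trials))
  bad <- function(cond, what) {
    if (any(cond))
      stop("invalid trial row(s) [", paste(head(row_id[cond], 5L),
           collapse = ", "), if (sum(cond) > 5L) ", ..." else "", "]: ", what)
  }
  bad(!is.finite(trials$n_left) | !is.finite(trials$n_right) |
        trials$n_left != round(trials$n_left) |
        trials$n_right != round(trials$n_right),
      "dot counts must be integers")
  bad(trials$n_left == trials$n_right, "n_left equals n_right")
  ratio <- .match_ratio(trials$n_left, trials$n_right)
  bad(is.na(ratio), "numerosity ratio not in the design set {4:3, 7:6, 9:8, 10:9}")
  bad(!(trials$response %in% c("left", "right")),
      "response must be 'left' or 'right'")
  bad(!is.finite(trials$rt) | trials$rt <= 0, "rt must be a positive number")
  bad(trials$rt > max_rt,
      sprintf("rt exceeds the %g s response window", max_rt))
  trials$ratio <- factor(ratio, levels = ans_ratio_levels())
  rownames(trials) <- NULL
  trials
}

#' Write trials to a delimited file
#'
#' Inverse of [read_trials()]: writes the canonical trial columns as CSV so a
#' write-then-read round trip reproduces the records.
#'
#' @param trials Validated trial data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  keep <- intersect(c(.trial_columns), names(trials))
  write.csv(trials[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse one participant's trials into ratio conditions
#'
#' Assigns every trial to its numerosity-ratio condition and collapses over
#' side: trials with the larger array on the left are combined with
#' mirror-image trials (larger array on the right) by recoding the response,
#' so that a trial is *correct* iff the chosen side held the larger
#' numerosity. Returns per-condition correct/error RT samples and counts.
#'
#' @param trials Data frame of one participant's validated trials.
#' @return An object of class `ans_conditions`: a named list over the four
#'   ratios, each with elements `ratio`, `n_l`, `n_s` (canonical integer
#'   ratio), `log_ratio`, `correct_rts`, `error_rts`, `n_correct`, `n_error`,
#'   and the pooled RT range (`rt_min`, `rt_max`, `NA` when empty).
#' @export
collapse_conditions <- function(trials) {
  if (nrow(trials) && length(unique(trials$participant_id)) > 1L)
    stop("collapse_conditions() expects trials from a single participant")
  if (!"ratio" %in% names(trials)) trials <- validate_trials(trials)
  out <- lapply(ans_ratio_levels(), function(r) {
    sub <- trials[!is.na(trials$ratio) & trials$ratio == r, , drop = FALSE]
    larger_left <- sub$n_left > sub$n_right
    correct <- (larger_left & sub$response == "left") |
               (!larger_left & sub$response == "right")
    rs <- .ans_ratios[[r]]
    structure(list(
      ratio = r, n_l = rs[1], n_s = rs[2],
      log_ratio = log(rs[1]) - log(rs[2]),
      correct_rts = sub$rt[correct],
      error_rts = sub$rt[!correct],
      n_correct = sum(correct), n_error = sum(!correct),
      rt_min = if (nrow(sub)) min(sub$rt) else NA_real_,
      rt_max = if (nrow(sub)) max(sub$rt) else NA_real_
    ), class = "ans_condition")
  })
  names(out) <- ans_ratio_levels()
  structure(out, class = "ans_conditions",
            n_trials = nrow(trials),
            participant_id = if (nrow(trials)) trials$participant_id[1] else NA)
}

#' @export
print.ans_conditions <- function(x, ...) {
  cat("Ratio conditions (", attr(x, "n_trials"), " trials)\n", sep = "")
  for (cond in x)
    cat(sprintf("  %5s: %4d correct, %3d error (accuracy %.3f)\n",
                cond$ratio, cond$n_correct, cond$n_error,
                cond$n_correct / max(1L, cond$n_correct + cond$n_error)))
  invisible(x)
}

#' Apply participant-level exclusion rules
#'
#' Excludes participants whose overall accuracy falls below `min_accuracy`
#' and/or who have more than `max_fast_fraction` of trials faster than
#' `fast_rt_cut` seconds, recording the reason(s) per excluded participant.
#'
#' @param trials Validated cohort trial data frame (all participants).
#' @param min_accuracy Minimum overall proportion correct (default 0.60).
#' @param fast_rt_cut Fast-guess RT threshold in seconds (default 0.250).
#' @param max_fast_fraction Maximum tolerated fraction of fast trials
#'   (default 0.10).
#' @return A list with `kept` (trial data frame of retained participants) and
#'   `excluded` (data frame with `participant_id`, `accuracy`,
#'   `fast_fraction`, `reason`).
#' @export
apply_exclusions <- function(trials, min_accuracy = 0.60,
                             fast_rt_cut = 0.250, max_fast_fraction = 0.10) {
  if (!"ratio" %in% names(trials)) trials <- validate_trials(trials)
  ids <- unique(trials$participant_id)
  larger_left <- trials$n_left > trials$n_right
  correct <- (larger_left & trials$response == "left") |
             (!larger_left & trials$response == "right")
  stats <- lapply(ids, function(id) {
    sel <- trials$participant_id == id
    if (!any(sel)) stop("participant with no trials: ", id)
    data.frame(participant_id = id,
               accuracy = mean(correct[sel]),
               fast_fraction = mean(trials$rt[sel] < fast_rt_cut))
  })
  stats <- do.call(rbind, stats)
  low_acc <- stats$accuracy < min_accuracy
  fast <- stats$fast_fraction > max_fast_fraction
  stats$reason <- ifelse(low_acc & fast, "accuracy; fast responses",
                  ifelse(low_acc, "accuracy",
                  ifelse(fast, "fast responses", "")))
  excluded <- stats[low_acc | fast, , drop = FALSE]
  rownames(excluded) <- NULL
  kept <- trials[!(trials$participant_id %in% excluded$participant_id), ,
                 drop = FALSE]
  list(kept = kept, excluded = excluded)
}
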