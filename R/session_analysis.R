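#' Performance metrics for a set of trials
#'
#' Computes the standard 5CSRTT performance measures:
#' \describe{
#'   \item{accuracy_pct}{correct / (correct + incorrect) x 100}
#'   \item{premature_pct}{premature / all trials x 100}
#'   \item{omission_pct}{omitted / (correct + incorrect + omitted) x 100 —
#'     prematurely terminated trials are excluded from the denominator}
#'   \item{mean_rt_s}{mean reaction time (cue onset to poke) over correct
#'     trials}
#' }
#' A metric whose denominator is zero is reported as NA.
#'
#' @param trials A trial-log tibble (rows from [run_session()] or
#'   [read_trial_log()]); only `outcome` and `reaction_time_s` are used.
#' @return A one-row tibble with counts and metrics.
#' @export
#' @examples
#' trials <- tibble::tibble(
#'   outcome = c(rep("correct", 40), rep("incorrect", 10),
#'               rep("omission", 5), rep("premature", 5)),
#'   reaction_time_s = c(rep(1, 40), rep(NA, 20)))
#' compute_metrics(trials)  # accuracy 80, premature 8.33, omission 9.09
compute_metrics <- function(trials) {
  n_correct <- sum(trials$outcome == "correct")
  n_incorrect <- sum(trials$outcome == "incorrect")
  n_omitted <- sum(trials$outcome == "omission")
  n_premature <- sum(trials$outcome == "premature")
  n_trials <- nrow(trials)
  acc_den <- n_correct + n_incorrect
  om_den <- n_correct + n_incorrect + n_omitted
  tibble::tibble(
    n_trials = n_trials, n_correct = n_correct, n_incorrect = n_incorrect,
    n_omitted = n_omitted, n_premature = n_premature,
    accuracy_pct = if (acc_den > 0) 100 * n_correct / acc_den else NA_real_,
    premature_pct = if (n_trials > 0) 100 * n_premature / n_trials else NA_real_,
    omission_pct = if (om_den > 0) 100 * n_omitted / om_den else NA_real_,
    mean_rt_s = if (n_correct > 0) {
      mean(trials$reaction_time_s[trials$outcome == "correct"])
    } else NA_real_
  )
}

#' Per-session performance metrics
#'
#' [compute_metrics()] applied per (mouse, session), keeping the session
#' metadata needed for daily aggregation.
#'
#' @param trials A trial-log tibble.
#' @return A tibble, one row per session with >= 1 logged trial.
#' @export
session_metrics <- function(trials) {
  if (nrow(trials) == 0) {
    return(tibble::tibble(mouse_id = character(), session_id = character(),
                          day = integer(), slot_hour = integer()))
  }
  trials |>
    dplyr::group_by(.data$mouse_id, .data$session_id) |>
    dplyr::group_modify(function(d, key) {
      dplyr::bind_cols(
        tibble::tibble(day = clock_day(min(d$trial_start_clock)),
                       slot_hour = d$slot_hour[1],
                       max_stage = max(d$stage)),
        compute_metrics(d))
    }) |>
    dplyr::ungroup()
}

#' Experiment day and hour-of-day from a clock value
#'
#' Clocks are seconds from experiment start (day 1, 00:00). `clock_day()`
#' gives the 1-based calendar day (day boundary at midnight), `clock_hour()`
#' the hour of day 0--23 used for circadian binning.
#'
#' @param clock Numeric seconds from experiment start.
#' @return Integer vector.
#' @export
clock_day <- function(clock) as.integer(clock %/% 86400) + 1L

#' @rdname clock_day
#' @export
clock_hour <- function(clock) as.integer((clock %% 86400) %/% 3600)

#' Daily performance aggregate
#'
#' Daily metrics are the unweighted mean of per-session metrics over that
#' calendar day's entered sessions with at least one logged trial (the
#' convention for multi-session automated training, where a day holds up to
#' 12 short sessions). `stage_reached` is the highest stage attained that
#' day. Days without any qualifying session are absent from the output. Set
#' `trial_weighted = TRUE` to weight sessions by trial count instead.
#'
#' @param trials A trial-log tibble for one or more mice.
#' @param trial_weighted Weight session metrics by their trial counts?
#' @return A tibble, one row per (mouse, day).
#' @export
daily_aggregate <- function(trials, trial_weighted = FALSE) {
  per_session <- session_metrics(trials)
  if (nrow(per_session) == 0) return(per_session)
  wmean <- function(x, w) {
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    stats::weighted.mean(x[ok], w[ok])
  }
  per_session |>
    dplyr::group_by(.data$mouse_id, .data$day) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      accuracy_pct = wmean(.data$accuracy_pct,
                           if (trial_weighted) .data$n_trials else rep(1, dplyr::n())),
      premature_pct = wmean(.data$premature_pct,
                            if (trial_weighted) .data$n_trials else rep(1, dplyr::n())),
      omission_pct = wmean(.data$omission_pct,
                           if (trial_weighted) .data$n_trials else rep(1, dplyr::n())),
      mean_rt_s = wmean(.data$mean_rt_s,
                        if (trial_weighted) .data$n_correct else rep(1, dplyr::n())),
      n_trials = sum(.data$n_trials),   # last: would shadow the weights above
      stage_reached = max(.data$max_stage),
      .groups = "drop"
    )
}

#' Sliding-window learning curve
#'
#' Windows the first `max_trials` completed trials of each mouse into
#' overlapping windows of `window_trials` trials (default 50 trials with 50
#' percent overlap, so window starts step by 25 trials: 0, 25, 50, ...). The
#' last window is the final one fully contained in `max_trials` (and in the
#' available trials), giving 27 windows for the canonical 700/50/0.5
#' setting. Each window is summarised with [compute_metrics()].
#'
#' @param trials Trial log ordered by completion (within mouse).
#' @param window_trials Window size in trials.
#' @param overlap_fraction Overlap between consecutive windows, in \[0, 1).
#' @param max_trials Number of initial trials to analyse.
#' @return A tibble of class `ats_learning_curve`: one row per (mouse,
#'   window), with `window`, `trial_start` (0-based), `trial_mid` and the
#'   metric columns. Mice with fewer trials than one window contribute no
#'   rows.
#' @export
learning_curve <- function(trials, window_trials = 50, overlap_fraction = 0.5,
                           max_trials = 700) {
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1,
            window_trials <= max_trials)
  step <- as.integer(round(window_trials * (1 - overlap_fraction)))
  out <- trials |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$trial_start_clock), ]
      n <- min(nrow(d), max_trials)
      if (n < window_trials) return(tibble::tibble())
      starts <- seq(0L, n - window_trials, by = step)
      purrr::map_dfr(seq_along(starts), function(i) {
        rows <- (starts[i] + 1L):(starts[i] + window_trials)
        dplyr::bind_cols(
          tibble::tibble(window = i, trial_start = starts[i],
                         trial_mid = starts[i] + window_trials / 2),
          compute_metrics(d[rows, ]))
      })
    }) |>
    dplyr::ungroup()
  class(out) <- c("ats_learning_curve", class(out))
  out
}

#' Circadian activity profile
#'
#' Entry probability by hour of day: for each mouse, scheduled gate openings
#' (opportunities) and detected entries are pooled across days per hour bin;
#' the cohort profile (default) then averages the per-mouse probabilities
#' across mice, so every animal counts equally regardless of how many days
#' it was observed.
#'
#' @param sessions A session-index tibble (from an experiment or
#'   [read_session_index()]); every row is one opportunity, `entered` marks
#'   entries.
#' @param by_mouse Return the per-mouse profile instead of the cohort
#'   average?
#' @return A tibble of class `ats_activity`: `hour`, `n_opportunities`,
#'   `n_entries`, `entry_probability` (plus `mouse_id` if `by_mouse`). Hours
#'   with no opportunities are absent.
#' @export
entry_probability_by_hour <- function(sessions, by_mouse = FALSE) {
  per_mouse <- sessions |>
    dplyr::group_by(.data$mouse_id, hour = .data$slot_hour) |>
    dplyr::summarise(n_opportunities = dplyr::n(),
                     n_entries = sum(.data$entered), .groups = "drop") |>
    dplyr::mutate(entry_probability = .data$n_entries / .data$n_opportunities)
  out <- if (by_mouse) {
    per_mouse
  } else {
    per_mouse |>
      dplyr::group_by(.data$hour) |>
      dplyr::summarise(n_opportunities = sum(.data$n_opportunities),
                       n_entries = sum(.data$n_entries),
                       entry_probability = mean(.data$entry_probability),
                       .groups = "drop")
  }
  class(out) <- c("ats_activity", class(out))
  out
}

#' Training-speed summaries: days / trials to reach a stage
#'
#' `days_to_stage()` reports, per mouse, the first 1-based experiment day on
#' which a trial was performed at (or above) the target stage;
#' `trials_to_stage()` the cumulative number of completed trials before the
#' first trial at (or above) the target stage. Mice that never reach the
#' stage get NA.
#'
#' @param trials A trial-log tibble.
#' @param target_stage Stage index to reach.
#' @return A tibble with `mouse_id` and `days_to_stage` / `trials_to_stage`.
#' @export
days_to_stage <- function(trials, target_stage) {
  trials |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(days_to_stage = first_at_stage(
      .data$stage, .data$trial_start_clock, target_stage,
      function(d, i) clock_day(d$clock[i])), .groups = "drop")
}

#' @rdname days_to_stage
#' @export
trials_to_stage <- function(trials, target_stage) {
  trials |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(trials_to_stage = first_at_stage(
      .data$stage, .data$trial_start_clock, target_stage,
      function(d, i) i - 1L), .groups = "drop")
}

first_at_stage <- function(stage, clock, target, extract) {
  ord <- order(clock)
  d <- list(stage = stage[ord], clock = clock[ord])
  i <- which(d$stage >= target)[1]
  if (is.na(i)) return(NA_integer_)
  as.integer(extract(d, i))
}

#' Stage timeline
#'
#' The stage in effect over time: one row per (mouse, day) with the first
#' and highest stage of that day's trials.
#'
#' @param trials A trial-log tibble.
#' @return A tibble with `mouse_id`, `day`, `stage_start`, `stage_end`.
#' @export
stage_timeline <- function(trials) {
  trials |>
    dplyr::mutate(day = clock_day(.data$trial_start_clock)) |>
    dplyr::group_by(.data$mouse_id, .data$day) |>
    dplyr::arrange(.data$trial_start_clock, .by_group = TRUE) |>
    dplyr::summarise(stage_start = dplyr::first(.data$stage),
                     stage_end = max(.data$stage), .groups = "drop")
}
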