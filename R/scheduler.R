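#' Daily schedule configuration
#'
#' Describes when the training chamber is offered to each mouse. In ATS mode
#' the motorized gate opens every `interval_h` hours for a 15-min session,
#' giving 24 / `interval_h` voluntary opportunities per day; the two home
#' cages attached to one chamber alternate with a phase offset so their open
#' intervals never overlap. Manual modes run one experimenter-started 30-min
#' session per day in the morning window.
#'
#' @param mode `"ATS"`, `"manual"` or `"manual_CWC"`.
#' @param session_len_s Session length; defaults to 900 s (ATS) or 1800 s
#'   (manual).
#' @param interval_h Hours between ATS gate openings (must divide 24).
#' @param manual_start_hour Start hour for manual sessions (09:00, inside the
#'   09:00--12:00 window).
#' @param lights_on_hour,lights_off_hour Light-phase boundaries (07:00 and
#'   19:00).
#' @param cage_offsets_h Phase offsets (hours) for the two cages of one
#'   chamber.
#' @param entry_window_s How long the gate waits for a voluntary entry before
#'   recording a skip.
#' @return A list of class `ats_schedule_config`.
#' @export
schedule_config <- function(mode = c("ATS", "manual", "manual_CWC"),
                            session_len_s = NULL, interval_h = 2,
                            manual_start_hour = 9, lights_on_hour = 7,
                            lights_off_hour = 19, cage_offsets_h = c(0, 1),
                            entry_window_s = 120) {
  mode <- match.arg(mode)
  cage_offsets_h <- as.numeric(unlist(cage_offsets_h))
  if (is.null(session_len_s)) {
    session_len_s <- if (mode == "ATS") 900 else 1800
  }
  if (24 %% interval_h != 0) {
    stop("interval_h must divide 24", call. = FALSE)
  }
  if (session_len_s >= interval_h * 3600) {
    stop("session_len_s must be shorter than the scheduling interval",
         call. = FALSE)
  }
  structure(list(mode = mode, session_len_s = session_len_s,
                 interval_h = interval_h,
                 manual_start_hour = manual_start_hour,
                 lights_on_hour = lights_on_hour,
                 lights_off_hour = lights_off_hour,
                 cage_offsets_h = cage_offsets_h,
                 entry_window_s = entry_window_s),
            class = "ats_schedule_config")
}

#' Water-access schedule
#'
#' Mode-specific water policy outside the task. ATS mice drink only in the
#' task (free water at session start plus rewards). Standard manual training
#' adds a free-water window of 2 h per day (14:00--16:00). The controlled
#' water consumption variant (manual_CWC) instead supplements each mouse to
#' a fixed daily total at 16:00.
#'
#' @param mode Training mode.
#' @param free_window_hours Start and end hour of the manual free-water
#'   window.
#' @param cwc_daily_total_ul Daily water total for manual_CWC (1.8 ml).
#' @param cwc_supplement_hour Hour of the CWC top-up.
#' @return A list of class `ats_water_config`.
#' @export
water_config <- function(mode = c("ATS", "manual", "manual_CWC"),
                         free_window_hours = c(14, 16),
                         cwc_daily_total_ul = 1800, cwc_supplement_hour = 16) {
  mode <- match.arg(mode)
  free_window_hours <- as.numeric(unlist(free_window_hours))
  if (cwc_daily_total_ul < 0) stop("water volumes must be nonnegative",
                                   call. = FALSE)
  structure(list(mode = mode, free_window_hours = free_window_hours,
                 cwc_daily_total_ul = cwc_daily_total_ul,
                 cwc_supplement_hour = cwc_supplement_hour),
            class = "ats_water_config")
}

#' Training break specification
#'
#' During a break no sessions are scheduled; at resumption each mouse
#' restarts exactly at the stage it had reached. `resume_mode =
#' "switch_to_manual"` moves the mouse to the manual schedule for all days
#' after the break (modelling transfer from automated to manual training).
#'
#' @param start_day First break day (1-based experiment day).
#' @param length_days Break length in days (>= 0).
#' @param resume_mode `"same_system"` or `"switch_to_manual"`.
#' @return A list of class `ats_break`.
#' @export
break_spec <- function(start_day, length_days,
                       resume_mode = c("same_system", "switch_to_manual")) {
  resume_mode <- match.arg(resume_mode)
  if (length_days < 0) stop("length_days must be >= 0", call. = FALSE)
  structure(list(start_day = as.integer(start_day),
                 length_days = as.integer(length_days),
                 resume_mode = resume_mode),
            class = "ats_break")
}

break_days <- function(brk) {
  if (brk$length_days == 0) return(integer())
  seq(brk$start_day, brk$start_day + brk$length_days - 1L)
}

#' Build one day's session slots
#'
#' ATS mode: one slot every `interval_h` hours per mouse, the second cage
#' phase-shifted by its offset. Manual modes: a single daily slot at the
#' manual start hour.
#'
#' @param config A [schedule_config()].
#' @param cage_offset_h Phase offset of this mouse's cage (hours).
#' @return A tibble with `slot` (1-based), `slot_hour` and `start_s` (seconds
#'   from midnight).
#' @export
build_day_schedule <- function(config, cage_offset_h = 0) {
  if (config$mode == "ATS") {
    hours <- seq(0, 23, by = config$interval_h) + cage_offset_h
    hours <- hours[hours < 24]
  } else {
    hours <- config$manual_start_hour
  }
  tibble::tibble(slot = seq_along(hours), slot_hour = as.integer(hours),
                 start_s = hours * 3600)
}

#' Gate events for one scheduled slot
#'
#' The gate opens at the slot start. If the mouse enters within the entry
#' window the entry is detected and the session runs to length; otherwise a
#' skip is recorded and the gate closes at the end of the entry window.
#'
#' @param slot_clock Gate-opening time, seconds from experiment start.
#' @param cage_id Cage identifier.
#' @param agent_entry Did the mouse enter?
#' @param config A [schedule_config()].
#' @return A tibble of gate events (`clock`, `cage_id`, `action`), actions in
#'   `open`, `entry_detected`, `skip`, `close`.
#' @export
gate_decision <- function(slot_clock, cage_id, agent_entry, config) {
  if (agent_entry) {
    tibble::tibble(
      clock = c(slot_clock, slot_clock, slot_clock + config$session_len_s),
      cage_id = cage_id,
      action = c("open", "entry_detected", "close")
    )
  } else {
    tibble::tibble(
      clock = c(slot_clock, slot_clock + config$entry_window_s,
                slot_clock + config$entry_window_s),
      cage_id = cage_id,
      action = c("open", "skip", "close")
    )
  }
}

# Deterministic 31-bit substream seed from the experiment seed and a string
# key, so each mouse owns an RNG stream independent of cohort composition.
substream_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(paste0("m:", key))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Run a multi-day, multi-mouse training experiment
#'
#' Orchestrates the full pipeline: for every experiment day and scheduled
#' slot, the gate opens, the agent decides whether to enter (circadian entry
#' probability for virtual mice; scripted agents always enter), and entered
#' sessions run the trial engine with criterion-gated stage advancement
#' carried across sessions. Break days schedule nothing and preserve each
#' mouse's stage exactly; a break with `resume_mode = "switch_to_manual"`
#' transfers the mouse to the manual schedule afterwards.
#'
#' Each mouse is simulated under its own deterministic RNG substream derived
#' from `seed` and its id, so results per mouse are invariant to cohort
#' composition. Mice are assigned to chambers in pairs with alternating cage
#' offsets.
#'
#' @param mouse_ids Character vector of mouse identifiers.
#' @param days Number of experiment days.
#' @param agents A single agent (recycled) or named list of agents
#'   (per mouse), from [virtual_mouse()] or [scripted_agent()].
#' @param stage_tbl A [stage_table()].
#' @param schedule A [schedule_config()].
#' @param water A [water_config()]; defaults to match the schedule mode.
#' @param breaks List of [break_spec()]s (non-overlapping).
#' @param stim_fraction Photostimulation fraction for all sessions
#'   (default 0).
#' @param free_water_ul_per_port Free water per port at session start.
#' @param perturbations Optional named list (by mouse id) of
#'   `list(day =, spec = perturbation_spec(...))` applied from the morning of
#'   `day` and ticked down per entered session.
#' @param break_skill_decay Per-break-day multiplicative skill decay in
#'   \[0, 1\] (default 0 = none).
#' @param seed Experiment seed.
#' @return An `ats_experiment` object: list with tibbles `trials`,
#'   `sessions`, `gate_events`, `water_events`, plus `final_states` and the
#'   configs.
#' @export
run_experiment <- function(mouse_ids, days, agents,
                           stage_tbl = stage_table(),
                           schedule = schedule_config(),
                           water = NULL,
                           breaks = list(), stim_fraction = 0,
                           free_water_ul_per_port = 15,
                           perturbations = list(),
                           break_skill_decay = 0, seed = 1) {
  if (inherits(agents, "ats_agent")) {
    agents <- stats::setNames(rep(list(agents), length(mouse_ids)), mouse_ids)
  }
  if (is.null(water)) water <- water_config(schedule$mode)
  if (inherits(breaks, "ats_break")) breaks <- list(breaks)
  all_break_days <- unlist(lapply(breaks, break_days))
  if (anyDuplicated(all_break_days)) {
    stop("breaks overlap", call. = FALSE)
  }

  trials <- list(); sessions <- list(); gates <- list(); waters <- list()
  states <- list()

  for (i in seq_along(mouse_ids)) {
    mid <- mouse_ids[i]
    agent <- agents[[mid]]
    cage_idx <- ((i - 1L) %% length(schedule$cage_offsets_h)) + 1L
    cage_id <- sprintf("S%d%s", ceiling(i / length(schedule$cage_offsets_h)),
                       LETTERS[cage_idx])
    offset <- schedule$cage_offsets_h[cage_idx]

    set.seed(substream_seed(seed, mid))
    state <- new_mouse_state(mid, params = agent$params)
    mtr <- list(); mse <- list(); mga <- list(); mwa <- list()
    mode <- schedule$mode
    pert <- perturbations[[mid]]

    for (day in seq_len(days)) {
      in_break <- any(vapply(breaks, function(b) day %in% break_days(b),
                             logical(1)))
      if (in_break) {
        if (break_skill_decay > 0 && !is.null(state$params)) {
          state$params$skill <- state$params$skill * (1 - break_skill_decay)
        }
        for (b in breaks) {
          if (b$resume_mode == "switch_to_manual" &&
              day == max(break_days(b))) {
            mode <- "manual"
          }
        }
        next
      }
      if (!is.null(pert) && day == pert$day && !is.null(state$params)) {
        state$params <- apply_perturbation(state$params, pert$spec)
      }
      day_sched <- if (mode == schedule$mode) schedule else
        schedule_config(mode)
      slots <- build_day_schedule(day_sched, cage_offset_h = offset)
      scfg <- session_config(mode = mode,
                             duration_s = day_sched$session_len_s,
                             free_water_ul_per_port = free_water_ul_per_port,
                             stim_fraction = stim_fraction)
      day0 <- (day - 1) * 86400

      for (k in seq_len(nrow(slots))) {
        slot_clock <- day0 + slots$start_s[k]
        p_entry <- if (is.null(state$params)) {
          agent$entry_prob(slots$slot_hour[k], NULL)
        } else {
          agent$entry_prob(slots$slot_hour[k], state$params)
        }
        entered <- if (p_entry >= 1) TRUE else stats::runif(1) < p_entry
        mga[[length(mga) + 1L]] <- gate_decision(slot_clock, cage_id, entered,
                                                 day_sched)
        sid <- sprintf("%s_d%03d_s%02d", mid, day, slots$slot[k])
        res <- run_session(state, stage_tbl, agent, scfg, entered = entered,
                           session_id = sid, slot_hour = slots$slot_hour[k],
                           start_clock = slot_clock)
        state <- res$state
        mse[[length(mse) + 1L]] <- res$session
        if (nrow(res$trials) > 0) mtr[[length(mtr) + 1L]] <- res$trials
        if (entered && !is.null(state$params)) {
          state$params <- tick_perturbation(state$params)
        }
      }

      # out-of-task water events for the manual schedules
      if (mode != "ATS" && water$mode != "manual_CWC") {
        mwa[[length(mwa) + 1L]] <- tibble::tibble(
          mouse_id = mid, day = day,
          clock = day0 + water$free_window_hours[1] * 3600,
          action = "free_access_window", volume_ul = NA_real_)
      } else if (mode != "ATS" && water$mode == "manual_CWC") {
        earned <- sum(vapply(mse, function(s)
          if (s$start_clock >= day0) s$free_water_ul else 0, numeric(1))) +
          sum(vapply(mtr, function(tr)
            sum(tr$reward_ul[tr$trial_start_clock >= day0]), numeric(1)))
        mwa[[length(mwa) + 1L]] <- tibble::tibble(
          mouse_id = mid, day = day,
          clock = day0 + water$cwc_supplement_hour * 3600,
          action = "cwc_supplement",
          volume_ul = max(0, water$cwc_daily_total_ul - earned))
      }
    }
    trials[[mid]] <- dplyr::bind_rows(mtr)
    sessions[[mid]] <- dplyr::bind_rows(mse)
    gates[[mid]] <- dplyr::bind_rows(mga)
    waters[[mid]] <- dplyr::bind_rows(mwa)
    states[[mid]] <- state
  }

  out <- list(
    trials = dplyr::bind_rows(trials) %||tbl%  empty_trial_log(),
    sessions = dplyr::bind_rows(sessions),
    gate_events = dplyr::bind_rows(gates),
    water_events = dplyr::bind_rows(waters),
    final_states = states,
    stage_tbl = stage_tbl, schedule = schedule, water = water,
    breaks = breaks, seed = seed
  )
  class(out) <- "ats_experiment"
  out
}

`%||tbl%` <- function(a, b) if (nrow(a) > 0) a else b

#' @export
print.ats_experiment <- function(x, ...) {
  cat("<ats_experiment>\n")
  cat("  mice:    ", length(x$final_states), "\n")
  cat("  sessions:", nrow(x$sessions),
      sprintf("(%d entered)", sum(x$sessions$entered)), "\n")
  cat("  trials:  ", nrow(x$trials), "\n")
  stages <- vapply(x$final_states, `[[`, integer(1), "stage")
  if (length(stages)) {
    cat("  final stages:", paste(stages, collapse = ", "), "\n")
  }
  invisible(x)
}
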