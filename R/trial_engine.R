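#' Select the next cue port from balanced pseudorandom blocks
#'
#' The light cue is presented at one of five ports in a pseudorandom order
#' that is balanced over consecutive blocks of five trials: within a block
#' each port is cued exactly once, in shuffled order. Given the cue ports
#' already used in the current (possibly partial) block, the next port is a
#' uniform draw from the block's remaining ports.
#'
#' @param history Integer vector of cue ports presented so far; only the
#'   current partial block (the last `length(history) %% 5` entries) matters.
#' @return A port index in 1..5.
#' @export
#' @examples
#' set.seed(1)
#' h <- integer()
#' for (i in 1:5) h <- c(h, select_cue_port(h))
#' sort(h)  # a permutation of 1:5
select_cue_port <- function(history = integer()) {
  k <- length(history) %% 5L
  used <- if (k > 0) utils::tail(history, k) else integer()
  remaining <- setdiff(1:5, used)
  remaining[sample.int(length(remaining), 1L)]
}

#' Assign photostimulation flags in balanced pseudorandom blocks
#'
#' Optogenetic stimulation is delivered before the cue on a fixed fraction of
#' trials, allocated pseudorandomly: flags are drawn by shuffling balanced
#' blocks whose size is the smallest integer at which the fraction is exact
#' (pairs for 0.5), so the realized fraction is exact over every complete
#' block. A trailing incomplete block is a truncated shuffled block.
#'
#' @param n_trials Number of trials to flag.
#' @param stim_fraction Proportion of stimulated trials in \[0, 1\];
#'   default 0.5.
#' @return A tibble with columns `trial` (1..n) and `stim` (logical).
#' @export
#' @examples
#' set.seed(1)
#' sum(assign_stimulation(100, 0.5)$stim)  # exactly 50
assign_stimulation <- function(n_trials, stim_fraction = 0.5) {
  if (stim_fraction < 0 || stim_fraction > 1) {
    stop("stim_fraction must lie in [0, 1]", call. = FALSE)
  }
  flags <- draw_stim_flags(n_trials, stim_fraction)
  tibble::tibble(trial = seq_len(n_trials), stim = flags)
}

# Smallest block size at which `fraction` of trials is a whole number.
stim_block_size <- function(fraction) {
  if (fraction %in% c(0, 1)) return(1L)
  for (b in 1:1000) {
    if (abs(b * fraction - round(b * fraction)) < 1e-9) return(as.integer(b))
  }
  1000L
}

# Vector of n stimulation flags from shuffled balanced blocks.
draw_stim_flags <- function(n, fraction) {
  if (n == 0) return(logical())
  if (fraction == 0) return(rep(FALSE, n))
  if (fraction == 1) return(rep(TRUE, n))
  b <- stim_block_size(fraction)
  k <- as.integer(round(b * fraction))
  template <- c(rep(TRUE, k), rep(FALSE, b - k))
  n_blocks <- ceiling(n / b)
  flags <- unlist(lapply(seq_len(n_blocks), function(i) sample(template)))
  flags[seq_len(n)]
}

# Classify a single trial. Internal, list-in/list-out so million-trial
# property sweeps stay cheap; run_trial() is the tibble-returning wrapper.
#
# Outcome rule, with t the first poke time from trial start:
#   t < iti                              -> premature (no cue shown)
#   iti <= t < iti + light_on + LH:
#     port == cue  -> correct, reaction time t - iti, reward by stage
#     port != cue  -> incorrect
#   no poke in the window                -> omission
# Every non-correct outcome ends with a house-light-off timeout.
classify_trial <- function(stage_row, iti_s, cue_port, response,
                           stim_flag = FALSE, timeout_s = 5) {
  poke_time <- response$poke_time_s
  poke_port <- response$poke_port
  has_poke <- !is.null(poke_time) && !is.na(poke_time)
  has_port <- !is.null(poke_port) && !is.na(poke_port)
  if (has_poke != has_port) {
    stop("malformed response: poke port must be present iff poke time is",
         call. = FALSE)
  }
  if (has_poke && poke_time < 0) {
    stop("malformed response: negative poke time", call. = FALSE)
  }
  window_end <- iti_s + stage_row$light_on_s + stage_row$limited_hold_s

  if (has_poke && poke_time < iti_s) {
    outcome <- "premature"
    response_port <- poke_port
    rt <- NA_real_
    reward <- 0
    duration <- poke_time + timeout_s
  } else if (has_poke && poke_time < window_end) {
    response_port <- poke_port
    if (poke_port == cue_port) {
      outcome <- "correct"
      rt <- poke_time - iti_s
      reward <- reward_volume(stage_row$stage)
      duration <- poke_time
    } else {
      outcome <- "incorrect"
      rt <- NA_real_
      reward <- 0
      duration <- poke_time + timeout_s
    }
  } else {
    outcome <- "omission"
    response_port <- NA_integer_
    rt <- NA_real_
    reward <- 0
    duration <- window_end + timeout_s
  }

  list(
    stage = stage_row$stage, iti_s = iti_s, cue_port = cue_port,
    response_port = if (is.null(response_port)) NA_integer_ else as.integer(response_port),
    outcome = outcome, reaction_time_s = rt, reward_ul = reward,
    timeout_applied = outcome != "correct", stim_flag = stim_flag,
    duration_s = duration
  )
}

#' Run one 5CSRTT trial
#'
#' Executes the trial state machine for a single trial: the inter-trial
#' interval (ITI), the light cue at `cue_port`, the limited hold, and the
#' 5-s timeout that punishes every non-correct outcome. The first poke of the
#' trial is classified; a poke during the ITI is premature (the cue is never
#' shown), a poke at the cued port while the cue or limited hold is active is
#' correct and rewarded, a poke at any other port in that window is
#' incorrect, and no poke at all is an omission.
#'
#' @param stage_row One row of a [stage_table()].
#' @param iti_s ITI duration in seconds; must be one of the stage's
#'   `iti_choices_s`.
#' @param cue_port Cued port, 1..5.
#' @param response The agent's response: a list with `poke_time_s` (seconds
#'   from trial start, or NA/NULL for no poke) and `poke_port` (1..5, present
#'   iff a poke time is).
#' @param stim_flag Logical photostimulation marker carried through to the
#'   record.
#' @param timeout_s Timeout duration, default 5 s.
#' @return A one-row tibble with the trial outcome, reaction time, reward and
#'   total trial duration.
#' @export
#' @examples
#' st <- stage_table()
#' run_trial(st[1, ], iti_s = 5, cue_port = 3,
#'           response = list(poke_time_s = 7, poke_port = 3))
run_trial <- function(stage_row, iti_s, cue_port, response, stim_flag = FALSE,
                      timeout_s = 5) {
  choices <- stage_row$iti_choices_s
  if (is.list(choices)) choices <- choices[[1]]
  if (!iti_s %in% choices) {
    stop("iti_s must be one of the stage's iti_choices_s", call. = FALSE)
  }
  rec <- classify_trial(stage_row, iti_s, cue_port, response, stim_flag,
                        timeout_s)
  tibble::as_tibble(rec)
}

#' Initial per-mouse training state
#'
#' Bundles everything the engine carries for one mouse across sessions: its
#' current stage, the outcome counters accumulated since the last
#' advancement, the agent parameters (including the evolving skill), the
#' partial cue-port block, and running totals.
#'
#' @param mouse_id Mouse identifier string.
#' @param params Agent parameters ([agent_params()]); may be NULL for
#'   scripted agents.
#' @param stage Starting stage, default 1.
#' @return A list of class `ats_mouse_state`.
#' @export
new_mouse_state <- function(mouse_id, params = NULL, stage = 1L) {
  structure(list(
    mouse_id = mouse_id,
    stage = as.integer(stage),
    counters = new_counters(),
    params = params,
    cue_history = integer(),   # ports used in the current balanced block
    stim_queue = logical(),    # unconsumed flags of the current stim block
    trials_completed = 0L,
    sessions_entered = 0L
  ), class = "ats_mouse_state")
}

#' Session configuration
#'
#' @param mode `"ATS"` (home-cage automated training, 15-min sessions),
#'   `"manual"` (experimenter-run 30-min daily sessions) or `"manual_CWC"`
#'   (manual with controlled water consumption).
#' @param duration_s Session length in seconds; defaults to 900 for ATS and
#'   1800 for the manual modes.
#' @param free_water_ul_per_port Free water delivered from each of the five
#'   ports at session start (default 15 ul, the midpoint of the 10--20 ul
#'   range). ATS sessions always deliver it; manual sessions only at stage 1.
#' @param timeout_s Punishment timeout, default 5 s.
#' @param stim_fraction Fraction of trials flagged for photostimulation
#'   (default 0 = no stimulation; 0.5 in optogenetic protocols).
#' @return A list of class `ats_session_config`.
#' @export
session_config <- function(mode = c("ATS", "manual", "manual_CWC"),
                           duration_s = NULL, free_water_ul_per_port = 15,
                           timeout_s = 5, stim_fraction = 0) {
  mode <- match.arg(mode)
  if (is.null(duration_s)) {
    duration_s <- if (mode == "ATS") 900 else 1800
  }
  structure(list(mode = mode, duration_s = duration_s,
                 free_water_ul_per_port = free_water_ul_per_port,
                 timeout_s = timeout_s, stim_fraction = stim_fraction),
            class = "ats_session_config")
}

#' Run one training session
#'
#' Runs trials back-to-back until the session clock runs out, starting with
#' the free-water event (every session in ATS mode; only at stage 1 in manual
#' mode). After every completed trial the stage counters are updated, the
#' agent's skill advances by its learning rule, and the entry criteria of the
#' next stage are evaluated, so a mouse can move up a stage mid-session. A
#' trial still in progress when the clock expires is aborted and excluded
#' from the log.
#'
#' @param state Mouse state from [new_mouse_state()] (or a previous session).
#' @param stage_tbl A [stage_table()].
#' @param agent An agent from [virtual_mouse()] or [scripted_agent()].
#' @param config A [session_config()].
#' @param entered Whether the mouse entered the chamber; a skipped session
#'   yields zero trials and zero water.
#' @param session_id,slot_hour,start_clock Session metadata stamped onto the
#'   records; `start_clock` is in seconds from experiment start.
#' @return A list with `session` (one-row tibble), `trials` (tibble, one row
#'   per completed trial) and the updated `state`.
#' @export
run_session <- function(state, stage_tbl, agent, config = session_config(),
                        entered = TRUE, session_id = "s1", slot_hour = NA,
                        start_clock = 0) {
  trials <- list()
  free_water <- 0
  if (entered) {
    state$sessions_entered <- state$sessions_entered + 1L
    if (config$mode == "ATS" || state$stage == 1L) {
      free_water <- config$free_water_ul_per_port * 5
    }
    elapsed <- 0
    idx <- 0L
    stage_row <- as.list(stage_tbl[state$stage, ])
    stage_row$iti_choices_s <- stage_row$iti_choices_s[[1]]
    repeat {
      if (elapsed >= config$duration_s) break
      iti <- sample_iti(stage_row)
      cue <- select_cue_port(state$cue_history)
      state$cue_history <- c(utils::tail(state$cue_history,
                                         length(state$cue_history) %% 5L), cue)
      if (config$stim_fraction > 0) {
        if (length(state$stim_queue) == 0) {
          b <- stim_block_size(config$stim_fraction)
          k <- as.integer(round(b * config$stim_fraction))
          state$stim_queue <- sample(c(rep(TRUE, k), rep(FALSE, b - k)))
        }
        stim <- state$stim_queue[1]
        state$stim_queue <- state$stim_queue[-1]
      } else {
        stim <- FALSE
      }
      response <- agent$respond(stage_row, iti, cue, state$params)
      rec <- classify_trial(stage_row, iti, cue, response, stim,
                            config$timeout_s)
      if (elapsed + rec$duration_s > config$duration_s) break  # aborted trial
      idx <- idx + 1L
      rec$trial_index <- idx - 1L
      rec$trial_start_clock <- start_clock + elapsed
      trials[[idx]] <- rec
      elapsed <- elapsed + rec$duration_s

      field <- switch(rec$outcome, correct = "correct", incorrect = "incorrect",
                      omission = "omitted", premature = "premature")
      state$counters[[field]] <- state$counters[[field]] + 1L
      state$trials_completed <- state$trials_completed + 1L
      if (isTRUE(agent$learns)) {
        state$params <- update_skill(state$params, rec$outcome)
      }
      if (state$stage < 12L &&
          criteria_met(stage_tbl[state$stage + 1L, ], state$counters)) {
        state$stage <- state$stage + 1L
        state$counters <- new_counters()
        stage_row <- as.list(stage_tbl[state$stage, ])
        stage_row$iti_choices_s <- stage_row$iti_choices_s[[1]]
      }
    }
  }

  trials_tbl <- bind_trial_records(trials, mouse_id = state$mouse_id,
                                   session_id = session_id,
                                   slot_hour = slot_hour)
  session_tbl <- tibble::tibble(
    session_id = session_id, mouse_id = state$mouse_id, mode = config$mode,
    start_clock = start_clock, duration_s = config$duration_s,
    slot_hour = slot_hour, entered = entered, free_water_ul = free_water,
    n_trials = nrow(trials_tbl)
  )
  list(session = session_tbl, trials = trials_tbl, state = state)
}

# Stack per-trial lists into the canonical trial-log tibble.
bind_trial_records <- function(trials, mouse_id, session_id, slot_hour) {
  if (length(trials) == 0) return(empty_trial_log())
  tibble::tibble(
    mouse_id = mouse_id,
    session_id = session_id,
    slot_hour = as.integer(slot_hour),
    trial_index = vapply(trials, `[[`, integer(1), "trial_index"),
    stage = vapply(trials, function(x) as.integer(x$stage), integer(1)),
    iti_s = vapply(trials, `[[`, numeric(1), "iti_s"),
    cue_port = vapply(trials, function(x) as.integer(x$cue_port), integer(1)),
    response_port = vapply(trials, `[[`, integer(1), "response_port"),
    outcome = vapply(trials, `[[`, character(1), "outcome"),
    reaction_time_s = vapply(trials, `[[`, numeric(1), "reaction_time_s"),
    reward_ul = vapply(trials, `[[`, numeric(1), "reward_ul"),
    stim_flag = vapply(trials, `[[`, logical(1), "stim_flag"),
    trial_start_clock = vapply(trials, `[[`, numeric(1), "trial_start_clock")
  )
}

# The canonical (empty) trial-log schema.
empty_trial_log <- function() {
  tibble::tibble(
    mouse_id = character(), session_id = character(), slot_hour = integer(),
    trial_index = integer(), stage = integer(), iti_s = numeric(),
    cue_port = integer(), response_port = integer(), outcome = character(),
    reaction_time_s = numeric(), reward_ul = numeric(), stim_flag = logical(),
    trial_start_clock = numeric()
  )
}
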