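# Shared fixtures: cheap agents and a direct trial simulator used by several
# suites. Everything is generated in code; no stored data.

# Virtual mouse that omits every trial (cheap sessions: 12 trials each at
# stage 1); useful when only entry behaviour matters.
omitting_params <- function(entry_prob_by_hour = default_circadian_curve()) {
  agent_params(entry_prob_by_hour = entry_prob_by_hour,
               premature_hazard_per_s = 0, omission_prob = 1,
               detect_floor = 0, detect_ceiling = 0, skill = 0,
               learning_rate = 0)
}

# Simulate n trials of a virtual mouse at a fixed stage (no engine session
# loop, no learning): returns the trial log as a tibble.
simulate_fixed_stage <- function(n, params, stage_idx = 5,
                                 stage_tbl = stage_table()) {
  stage_row <- as.list(stage_tbl[stage_idx, ])
  stage_row$iti_choices_s <- stage_row$iti_choices_s[[1]]
  recs <- vector("list", n)
  history <- integer()
  for (i in seq_len(n)) {
    iti <- sample_iti(stage_row)
    cue <- select_cue_port(history)
    history <- c(utils::tail(history, length(history) %% 5L), cue)
    resp <- plan_trial_response(stage_row, iti, cue, params)
    recs[[i]] <- run_trial(stage_row, iti, cue, resp)
  }
  dplyr::bind_rows(recs)
}

# Independent single-pass recount of the performance metrics, written as a
# plain tally loop so it shares no code with compute_metrics().
recount_metrics <- function(trials) {
  nc <- ni <- no <- np <- 0L
  rt_sum <- 0
  for (k in seq_len(nrow(trials))) {
    o <- trials$outcome[k]
    if (o == "correct") {
      nc <- nc + 1L
      rt_sum <- rt_sum + trials$reaction_time_s[k]
    } else if (o == "incorrect") ni <- ni + 1L
    else if (o == "omission") no <- no + 1L
    else np <- np + 1L
  }
  list(
    accuracy = if (nc + ni > 0) 100 * nc / (nc + ni) else NA_real_,
    premature = if (nrow(trials) > 0) 100 * np / nrow(trials) else NA_real_,
    omission = if (nc + ni + no > 0) 100 * no / (nc + ni + no) else NA_real_,
    mean_rt = if (nc > 0) rt_sum / nc else NA_real_
  )
}
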