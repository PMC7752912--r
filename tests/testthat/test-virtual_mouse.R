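test_that("entry decisions follow the hourly probabilities", {
  p <- agent_params()
  p$entry_prob_by_hour[] <- 0
  p$entry_prob_by_hour[1] <- 1
  p$entry_prob_by_hour[16] <- 0.52   # hour 15
  set.seed(2)
  expect_true(all(replicate(50, entry_decision(0, p))))
  expect_false(any(replicate(50, entry_decision(3, p))))
  rate <- mean(replicate(10000, entry_decision(15, p)))
  expect_lt(abs(rate - 0.52), 0.015)
})

test_that("the default circadian curve dips to 0.52 at 15:00 and peaks late", {
  curve <- default_circadian_curve()
  expect_length(curve, 24)
  expect_equal(unname(curve[16]), 0.52)
  expect_equal(unname(which.min(curve)) - 1L, 15L)
  expect_equal(unname(curve[24]), 0.94)
  expect_true(all(curve >= 0 & curve <= 1))
})

test_that("detection is monotone in cue duration and skill", {
  p <- agent_params(skill = 0.5)
  expect_gte(detect_prob(30, p), detect_prob(0.5, p))
  durations <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1, 1.25, 2.5, 5, 10, 20, 30)
  probs <- vapply(durations, detect_prob, numeric(1), params = p)
  expect_true(all(diff(probs) >= 0))
  p_lo <- agent_params(skill = 0.2); p_hi <- agent_params(skill = 0.9)
  expect_gt(detect_prob(1, p_hi), detect_prob(1, p_lo))
})

test_that("degenerate parameters force the expected outcomes", {
  st <- stage_table()
  row1 <- as.list(st[1, ]); row1$iti_choices_s <- row1$iti_choices_s[[1]]
  set.seed(4)
  # no hazard, no detection, certain omission -> never pokes
  p <- agent_params(premature_hazard_per_s = 0, omission_prob = 1,
                    detect_floor = 0, detect_ceiling = 0, skill = 0)
  for (i in 1:20) {
    r <- plan_trial_response(row1, 5, cue_port = 3, p)
    expect_true(is.na(r$poke_time_s))
  }
  # perfect agent -> always correct
  p <- agent_params(premature_hazard_per_s = 0, skill = 1, detect_floor = 1,
                    detect_ceiling = 1, wrong_port_prob = 0)
  for (i in 1:20) {
    tr <- run_trial(row1, 5, 3, plan_trial_response(row1, 5, 3, p))
    expect_equal(tr$outcome, "correct")
  }
})

test_that("premature rate matches the exponential hazard closed form", {
  st <- stage_table()
  row <- as.list(st[4, ]); row$iti_choices_s <- row$iti_choices_s[[1]]
  hazard <- 0.1
  p <- agent_params(premature_hazard_per_s = hazard, omission_prob = 1,
                    detect_floor = 0, detect_ceiling = 0, skill = 0)
  set.seed(8)
  n <- 20000
  hits <- 0
  for (i in 1:n) {
    r <- plan_trial_response(row, 4, 1, p)
    if (!is.na(r$poke_time_s) && r$poke_time_s < 4) hits <- hits + 1
  }
  expected <- 1 - exp(-hazard * 4)   # 0.3297
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(hits / n - expected), 4 * se)
})

test_that("skill accumulates per completed trial and saturates at 1", {
  p <- agent_params(skill = 0.2, learning_rate = 0.001)
  for (i in 1:700) p <- update_skill(p, "omission")
  expect_equal(p$skill, 0.9)
  p$learning_rate <- 0
  expect_equal(update_skill(p)$skill, 0.9)
  p$skill <- 1; p$learning_rate <- 0.5
  expect_equal(update_skill(p)$skill, 1)
  # reward-gated variant ignores non-correct outcomes
  p <- agent_params(skill = 0.5, learning_rate = 0.1)
  expect_equal(update_skill(p, "omission", reward_gated = TRUE)$skill, 0.5)
  expect_equal(update_skill(p, "correct", reward_gated = TRUE)$skill, 0.6)
})

test_that("with learning on, accuracy rises with trial index in expectation", {
  set.seed(14)
  p <- agent_params(skill = 0.1, learning_rate = 0.002,
                    premature_hazard_per_s = 0)
  tr <- local({
    state_p <- p
    recs <- vector("list", 2000)
    st <- stage_table()
    row <- as.list(st[5, ]); row$iti_choices_s <- row$iti_choices_s[[1]]
    for (i in seq_len(2000)) {
      resp <- plan_trial_response(row, 4, cue_port = 3, state_p)
      recs[[i]] <- run_trial(row, 4, 3, resp)
      state_p <- update_skill(state_p)
    }
    dplyr::bind_rows(recs)
  })
  first <- compute_metrics(tr[1:500, ])
  last <- compute_metrics(tr[1501:2000, ])
  expect_gt(last$accuracy_pct, first$accuracy_pct)
  expect_lt(last$omission_pct, first$omission_pct)
})

test_that("perturbations adjust a copy and expire on schedule", {
  p <- agent_params()
  spec <- perturbation_spec("scopolamine_like", duration_sessions = 1)
  q <- apply_perturbation(p, spec)
  expect_gt(q$wrong_port_prob, p$wrong_port_prob)
  expect_gt(q$premature_hazard_per_s, p$premature_hazard_per_s)
  expect_equal(p, agent_params())  # original untouched
  # identity spec changes nothing
  id <- perturbation_spec("scopolamine_like", accuracy_delta = 0,
                          premature_delta = 0, omission_delta = 0,
                          learning_rate_factor = 1)
  expect_equal(validate_agent_params(apply_perturbation(p, id))[names(p)],
               p[names(p)], ignore_attr = TRUE)
  # after one entered session the baseline returns (skill carried over)
  q$skill <- 0.77
  back <- tick_perturbation(q)
  expect_equal(back$wrong_port_prob, p$wrong_port_prob)
  expect_equal(back$skill, 0.77)
  expect_null(attr(back, "sessions_remaining"))
  # parameters stay clipped to valid ranges
  extreme <- perturbation_spec("scopolamine_like", accuracy_delta = -500,
                               premature_delta = -10)
  r <- apply_perturbation(p, extreme)
  expect_lte(r$wrong_port_prob, 1)
  expect_gte(r$premature_hazard_per_s, 0)
  expect_error(apply_perturbation(p, list(name = "unknown")), "unknown")
  # stim_learning_delay slows the learning rate
  s <- apply_perturbation(p, perturbation_spec("stim_learning_delay"))
  expect_lt(s$learning_rate, p$learning_rate)
})

test_that("scripted agents implement their policies", {
  st <- stage_table()
  res <- run_session(new_mouse_state("m"), st, scripted_agent("always_correct"),
                     session_config("ATS"))
  expect_true(all(res$trials$outcome == "correct"))
  res <- run_session(new_mouse_state("m"), st, scripted_agent("never_poke"),
                     session_config("ATS"))
  expect_true(all(res$trials$outcome == "omission"))
  res <- run_session(new_mouse_state("m"), st,
                     scripted_agent("always_premature"), session_config("ATS"))
  expect_true(all(res$trials$outcome == "premature"))
  expect_error(scripted_agent("nope"), "'arg'")
})
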