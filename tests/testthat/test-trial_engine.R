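test_that("cue ports come in balanced shuffled blocks of five", {
  set.seed(3)
  h <- integer()
  for (i in 1:5) h <- c(h, select_cue_port(h))
  expect_setequal(h, 1:5)
  # exact balance over complete blocks
  for (i in 1:995) h <- c(h, select_cue_port(h))
  expect_equal(as.integer(table(h)), rep(200L, 5))
  # determinism under a fixed seed
  draw_seq <- function() {
    set.seed(99)
    s <- integer()
    for (i in 1:37) s <- c(s, select_cue_port(s))
    s
  }
  expect_identical(draw_seq(), draw_seq())
})

test_that("trial classification follows the outcome rules", {
  st <- stage_table()
  # correct poke at the cued port 2 s after cue onset, stage-1 reward 6 ul
  tr <- run_trial(st[1, ], iti_s = 5, cue_port = 3,
                  response = list(poke_time_s = 7, poke_port = 3))
  expect_equal(tr$outcome, "correct")
  expect_equal(tr$reaction_time_s, 2)
  expect_equal(tr$reward_ul, 6)
  expect_false(tr$timeout_applied)
  # poke during the ITI is premature regardless of port
  tr <- run_trial(st[1, ], iti_s = 5, cue_port = 3,
                  response = list(poke_time_s = 2, poke_port = 3))
  expect_equal(tr$outcome, "premature")
  expect_true(tr$timeout_applied)
  expect_equal(tr$reward_ul, 0)
  expect_true(is.na(tr$reaction_time_s))
  # no poke at stage 12, ITI 3: omission once the 3 + 0.5 + 5 = 8.5 s
  # window lapses, then the 5-s timeout
  tr <- run_trial(st[12, ], iti_s = 3, cue_port = 1,
                  response = list(poke_time_s = NA, poke_port = NA))
  expect_equal(tr$outcome, "omission")
  expect_true(tr$timeout_applied)
  expect_equal(tr$duration_s, 8.5 + 5)
  # wrong-port poke during the response window is incorrect
  tr <- run_trial(st[4, ], iti_s = 4, cue_port = 2,
                  response = list(poke_time_s = 6, poke_port = 5))
  expect_equal(tr$outcome, "incorrect")
  expect_true(tr$timeout_applied)
  # malformed responses are rejected
  expect_error(run_trial(st[1, ], 5, 3, list(poke_time_s = -1, poke_port = 2)),
               "negative")
  expect_error(run_trial(st[1, ], 5, 3, list(poke_time_s = NA, poke_port = 2)),
               "malformed")
  expect_error(run_trial(st[3, ], 7, 3, list(poke_time_s = NA, poke_port = NA)),
               "iti_choices")
})

test_that("stimulation flags are exact on complete blocks", {
  set.seed(5)
  plan <- assign_stimulation(100, 0.5)
  expect_equal(sum(plan$stim), 50)
  expect_true(all(!assign_stimulation(40, 0)$stim))
  expect_true(all(assign_stimulation(40, 1)$stim))
  # every consecutive pair holds exactly one stimulated trial
  expect_true(all(vapply(seq(1, 99, 2),
                         function(i) sum(plan$stim[i:(i + 1)]) == 1,
                         logical(1))))
  # incomplete final block: 7 trials at 0.5 give 3 or 4 flags
  for (i in 1:20) {
    expect_true(sum(assign_stimulation(7, 0.5)$stim) %in% c(3, 4))
  }
  # 20% in blocks of five
  expect_equal(sum(assign_stimulation(250, 0.2)$stim), 50)
  expect_error(assign_stimulation(10, 1.2), "\\[0, 1\\]")
})

test_that("a session advances stages exactly at criterion", {
  st <- stage_table()
  set.seed(7)
  res <- run_session(new_mouse_state("m"), st, scripted_agent("always_correct"),
                     session_config("ATS"))
  tr <- res$trials
  # 30 correct at stage 1 trigger entry to stage 2 on the next trial
  expect_equal(sum(tr$stage == 1), 30)
  expect_equal(tr$stage[31], 2L)
  expect_true(all(diff(tr$stage) >= 0))
  # rewards follow the stage of each trial
  expect_equal(tr$reward_ul, c(6, 5, 4)[pmin(tr$stage, 3)])
})

test_that("a never-poking mouse logs only omissions and fills the clock", {
  st <- stage_table()
  set.seed(7)
  res <- run_session(new_mouse_state("m"), st, scripted_agent("never_poke"),
                     session_config("ATS"))
  # stage-1 omission trial lasts 5 + 30 + 30 + 5 = 70 s; 900-s session
  # fits floor(900/70) = 12 complete trials, the 13th is aborted
  expect_equal(nrow(res$trials), 12)
  expect_true(all(res$trials$outcome == "omission"))
  expect_true(all(is.na(res$trials$response_port)))
  expect_equal(res$session$n_trials, 12)
})

test_that("skipped sessions log no trials and no water", {
  st <- stage_table()
  res <- run_session(new_mouse_state("m"), st, scripted_agent("always_correct"),
                     session_config("ATS"), entered = FALSE)
  expect_equal(nrow(res$trials), 0)
  expect_equal(res$session$free_water_ul, 0)
  expect_false(res$session$entered)
})

test_that("free water is delivered every ATS session but only at manual stage 1", {
  st <- stage_table()
  ats <- run_session(new_mouse_state("m", stage = 5), st,
                     scripted_agent("never_poke"), session_config("ATS"))
  expect_equal(ats$session$free_water_ul, 15 * 5)
  man1 <- run_session(new_mouse_state("m", stage = 1), st,
                      scripted_agent("never_poke"), session_config("manual"))
  expect_equal(man1$session$free_water_ul, 15 * 5)
  man5 <- run_session(new_mouse_state("m", stage = 5), st,
                      scripted_agent("never_poke"), session_config("manual"))
  expect_equal(man5$session$free_water_ul, 0)
})

test_that("session logs satisfy the outcome-partition and water invariants", {
  st <- stage_table()
  set.seed(21)
  state <- new_mouse_state("m", params = agent_params())
  agent <- virtual_mouse(state$params)
  for (k in 1:5) {
    res <- run_session(state, st, agent, session_config("ATS"),
                       session_id = paste0("s", k))
    state <- res$state
    tr <- res$trials
    m <- compute_metrics(tr)
    expect_equal(m$n_correct + m$n_incorrect + m$n_omitted + m$n_premature,
                 nrow(tr))
    # reaction time present iff correct, within the response window
    expect_identical(!is.na(tr$reaction_time_s), tr$outcome == "correct")
    ok <- tr$outcome == "correct"
    win <- st$light_on_s[tr$stage] + st$limited_hold_s[tr$stage]
    expect_true(all(tr$reaction_time_s[ok] > 0 &
                      tr$reaction_time_s[ok] <= win[ok]))
    # reward iff correct
    expect_identical(tr$reward_ul > 0, tr$outcome == "correct")
    # session water = free water + earned rewards
    expect_equal(res$session$free_water_ul + sum(tr$reward_ul),
                 75 + sum(ifelse(ok, c(6, 5, 4)[pmin(tr$stage, 3)], 0)))
  }
})

test_that("identical seeds replay identical trial streams", {
  st <- stage_table()
  once <- function() {
    set.seed(123)
    state <- new_mouse_state("m", params = agent_params())
    run_session(state, st, virtual_mouse(), session_config("ATS"))$trials
  }
  expect_identical(once(), once())
})
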