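mk_trials <- function(correct = 0, incorrect = 0, omitted = 0, premature = 0,
                      rt = 1) {
  tibble::tibble(
    outcome = c(rep("correct", correct), rep("incorrect", incorrect),
                rep("omission", omitted), rep("premature", premature)),
    reaction_time_s = c(rep(rt, correct),
                        rep(NA_real_, incorrect + omitted + premature)))
}

test_that("metrics follow the standard 5CSRTT formulas", {
  m <- compute_metrics(mk_trials(40, 10, 5, 5))
  expect_equal(m$accuracy_pct, 80)            # 40 / 50 x 100
  expect_equal(m$premature_pct, 100 * 5 / 60) # 8.333; all trials
  expect_equal(m$omission_pct, 100 * 5 / 55)  # 9.091; prematures excluded
  expect_equal(m$n_trials, 60)

  all_correct <- compute_metrics(mk_trials(25))
  expect_equal(all_correct$accuracy_pct, 100)
  expect_equal(all_correct$premature_pct, 0)
  expect_equal(all_correct$omission_pct, 0)
  expect_equal(all_correct$mean_rt_s, 1)

  only_prem <- compute_metrics(mk_trials(premature = 8))
  expect_true(is.na(only_prem$accuracy_pct))
  expect_equal(only_prem$premature_pct, 100)
  expect_true(is.na(only_prem$omission_pct))
  expect_true(is.na(only_prem$mean_rt_s))

  empty <- compute_metrics(mk_trials())
  expect_equal(empty$n_trials, 0)
  expect_true(is.na(empty$accuracy_pct))
})

test_that("metrics agree with an independent recount on random logs", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(1:2000, 1)
    trials <- tibble::tibble(
      outcome = sample(c("correct", "incorrect", "omission", "premature"),
                       n, replace = TRUE, prob = stats::runif(4)),
      reaction_time_s = NA_real_)
    trials$reaction_time_s[trials$outcome == "correct"] <-
      stats::runif(sum(trials$outcome == "correct"), 0.1, 5)
    m <- compute_metrics(trials)
    o <- recount_metrics(trials)
    expect_equal(m$accuracy_pct, o$accuracy)
    expect_equal(m$premature_pct, o$premature)
    expect_equal(m$omission_pct, o$omission)
    expect_equal(m$mean_rt_s, o$mean_rt)
  }
})

test_that("daily aggregation is an unweighted mean over entered sessions", {
  trials <- dplyr::bind_rows(
    tibble::tibble(mouse_id = "m", session_id = "s1", slot_hour = 1L,
                   stage = 3L, trial_start_clock = 3600 + seq(0, 90, 10),
                   outcome = c(rep("correct", 6), rep("incorrect", 4)),
                   reaction_time_s = c(rep(1, 6), rep(NA, 4))),
    tibble::tibble(mouse_id = "m", session_id = "s2", slot_hour = 3L,
                   stage = 4L, trial_start_clock = 3 * 3600 + seq(0, 40, 10),
                   outcome = c(rep("correct", 4), "incorrect"),
                   reaction_time_s = c(rep(2, 4), NA)))
  daily <- daily_aggregate(trials)
  expect_equal(nrow(daily), 1)
  expect_equal(daily$accuracy_pct, mean(c(60, 80)))  # 70, not trial-weighted
  expect_equal(daily$stage_reached, 4L)
  expect_equal(daily$n_trials, 15)
  # trial-weighted alternative
  daily_w <- daily_aggregate(trials, trial_weighted = TRUE)
  expect_equal(daily_w$accuracy_pct, (60 * 10 + 80 * 5) / 15)
  # a single session aggregates to itself
  one <- daily_aggregate(trials[trials$session_id == "s1", ])
  expect_equal(one$accuracy_pct, 60)
  # replicated identical sessions equal the single-session metrics
  rep3 <- dplyr::bind_rows(lapply(1:3, function(k) {
    d <- trials[trials$session_id == "s1", ]
    d$session_id <- paste0("r", k)
    d$trial_start_clock <- d$trial_start_clock + k * 7200
    d
  }))
  expect_equal(daily_aggregate(rep3)$accuracy_pct, 60)
  # no qualifying sessions -> day absent
  expect_equal(nrow(daily_aggregate(trials[0, ])), 0)
})

test_that("learning-curve windows tile the first 700 trials as specified", {
  set.seed(23)
  trials <- tibble::tibble(
    mouse_id = "m", trial_start_clock = seq_len(800),
    outcome = sample(c("correct", "incorrect"), 800, replace = TRUE),
    reaction_time_s = NA_real_)
  lc <- learning_curve(trials)
  expect_equal(nrow(lc), 27)                       # (700 - 50)/25 + 1
  expect_equal(lc$trial_start, seq(0, 650, by = 25))
  # window k covers trials [25k, 25k + 50)
  for (k in c(1, 13, 27)) {
    rows <- (lc$trial_start[k] + 1):(lc$trial_start[k] + 50)
    expect_equal(lc$accuracy_pct[k],
                 compute_metrics(trials[rows, ])$accuracy_pct)
  }
  # exactly one window with exactly window-many trials
  expect_equal(nrow(learning_curve(trials[1:50, ])), 1)
  # fewer trials than a window -> empty series
  expect_equal(nrow(learning_curve(trials[1:49, ])), 0)
})

test_that("a fixed-accuracy agent yields a flat learning curve", {
  st <- stage_table()
  set.seed(29)
  state <- new_mouse_state("m")
  agent <- scripted_agent("fixed_accuracy", p = 0.8)
  logs <- list()
  for (k in 1:12) {
    res <- run_session(state, st, agent, session_config("ATS"),
                       session_id = sprintf("s%02d", k),
                       start_clock = (k - 1) * 7200)
    # hold the ladder fixed so only sampling noise moves the curve
    res$state$stage <- 1L
    res$state$counters <- new_counters()
    state <- res$state
    logs[[k]] <- res$trials
  }
  trials <- dplyr::bind_rows(logs)
  expect_gt(nrow(trials), 700)
  lc <- learning_curve(trials)
  expect_equal(nrow(lc), 27)
  expect_true(all(abs(lc$accuracy_pct - 80) < 20))  # 50-trial binomial noise
  expect_lt(abs(mean(lc$accuracy_pct) - 80), 5)
})

test_that("activity profiles recover entry opportunities and entries", {
  sessions <- tidyr::expand_grid(mouse_id = c("a", "b"), day = 1:3,
                                 slot_hour = seq(0L, 22L, 2L)) |>
    dplyr::mutate(entered = (slot_hour + day) %% 4 != 0,
                  start_clock = (day - 1) * 86400 + slot_hour * 3600)
  prof <- entry_probability_by_hour(sessions)
  expect_equal(nrow(prof), 12)
  expect_equal(unique(prof$n_opportunities), 6L)   # 2 mice x 3 days
  by_mouse <- entry_probability_by_hour(sessions, by_mouse = TRUE)
  expect_equal(nrow(by_mouse), 24)
  expect_true(all(by_mouse$n_entries <= by_mouse$n_opportunities))
  # all-enter cohort has probability 1 everywhere
  sessions$entered <- TRUE
  expect_true(all(entry_probability_by_hour(sessions)$entry_probability == 1))
})

test_that("days- and trials-to-stage read off the first advancement", {
  exp <- run_experiment("m1", days = 1,
                        agents = scripted_agent("always_correct"), seed = 2)
  # stage 2 entry requires exactly 30 correct trials
  expect_equal(trials_to_stage(exp$trials, 2)$trials_to_stage, 30L)
  expect_equal(days_to_stage(exp$trials, 2)$days_to_stage, 1L)
  # a stage never reached is NA
  never <- run_experiment("m2", days = 1,
                          agents = scripted_agent("never_poke"), seed = 2)
  expect_true(is.na(days_to_stage(never$trials, 3)$days_to_stage))
})

test_that("stage timelines track per-day first and best stages", {
  exp <- run_experiment("m1", days = 2,
                        agents = scripted_agent("always_correct"), seed = 2)
  tl <- stage_timeline(exp$trials)
  expect_equal(nrow(tl), 2)
  expect_true(all(tl$stage_end >= tl$stage_start))
  expect_equal(tl$stage_start[2], 12L)  # the ladder tops out on day 1
})
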