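#' Write / read trial logs
#'
#' The trial log is one CSV per experiment, one row per trial, with exactly
#' the columns `mouse_id, session_id, slot_hour, trial_index, stage, iti_s,
#' cue_port, response_port, outcome, reaction_time_s, reward_ul, stim_flag,
#' trial_start_clock` (header mandatory, missing values as empty fields,
#' UTF-8, '.' decimal). Round-trips are lossless, including NA fields.
#'
#' @param trials A trial-log tibble.
#' @param path CSV path.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   the validated tibble.
#' @export
write_trial_log <- function(trials, path) {
  cols <- names(empty_trial_log())
  missing <- setdiff(cols, names(trials))
  if (length(missing) > 0) {
    stop("trial log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(trials[, cols], path, na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  spec <- readr::cols(
    mouse_id = readr::col_character(), session_id = readr::col_character(),
    slot_hour = readr::col_integer(), trial_index = readr::col_integer(),
    stage = readr::col_integer(), iti_s = readr::col_double(),
    cue_port = readr::col_integer(), response_port = readr::col_integer(),
    outcome = readr::col_character(), reaction_time_s = readr::col_double(),
    reward_ul = readr::col_double(), stim_flag = readr::col_logical(),
    trial_start_clock = readr::col_double()
  )
  trials <- readr::read_csv(path, col_types = spec, na = "",
                            progress = FALSE)
  unknown <- setdiff(names(trials), names(empty_trial_log()))
  if (length(unknown) > 0) {
    stop("unknown trial-log column: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!trials$outcome %in%
                 c("correct", "incorrect", "premature", "omission"))
  if (length(bad) > 0) {
    stop("malformed outcome token at row ", bad[1], ": '",
         trials$outcome[bad[1]], "'", call. = FALSE)
  }
  trials
}

#' Write / read the session index
#'
#' One row per scheduled session (entered or skipped): `session_id,
#' mouse_id, mode, start_clock, duration_s, slot_hour, entered,
#' free_water_ul, n_trials`.
#'
#' @param sessions A session-index tibble.
#' @param path CSV path.
#' @return The path (write) or the tibble (read).
#' @export
write_session_index <- function(sessions, path) {
  readr::write_csv(sessions, path, na = "")
  invisible(path)
}

#' @rdname write_session_index
#' @export
read_session_index <- function(path) {
  readr::read_csv(path, na = "", progress = FALSE, col_types = readr::cols(
    session_id = readr::col_character(), mouse_id = readr::col_character(),
    mode = readr::col_character(), start_clock = readr::col_double(),
    duration_s = readr::col_double(), slot_hour = readr::col_integer(),
    entered = readr::col_logical(), free_water_ul = readr::col_double(),
    n_trials = readr::col_integer()))
}

#' Experiment configuration
#'
#' A single document bundling everything needed to reproduce a simulation:
#' the schedule, the water schedule, the stage table, per-mouse agent
#' parameters, training breaks and the seed. Omitted fields are filled with
#' the canonical defaults. Round-trips losslessly through YAML.
#'
#' @param mouse_ids Mouse identifiers.
#' @param days Experiment length in days.
#' @param schedule A [schedule_config()].
#' @param water A [water_config()] (defaults to the schedule's mode).
#' @param stage_tbl A [stage_table()].
#' @param agent Agent parameters applied to every mouse
#'   ([agent_params()]).
#' @param breaks List of [break_spec()]s.
#' @param stim_fraction Photostimulation fraction.
#' @param seed Experiment seed.
#' @return A list of class `ats_experiment_config`.
#' @export
experiment_config <- function(mouse_ids = c("m1", "m2"), days = 7,
                              schedule = schedule_config(), water = NULL,
                              stage_tbl = stage_table(),
                              agent = agent_params(), breaks = list(),
                              stim_fraction = 0, seed = 1) {
  if (is.null(water)) water <- water_config(schedule$mode)
  structure(list(mouse_ids = mouse_ids, days = days, schedule = schedule,
                 water = water, stage_tbl = validate_stage_table(stage_tbl),
                 agent = validate_agent_params(agent), breaks = breaks,
                 stim_fraction = stim_fraction, seed = as.integer(seed)),
            class = "ats_experiment_config")
}

#' Load / save an experiment configuration
#'
#' YAML with sections `mouse_ids`, `days`, `schedule`, `water`, `stages`,
#' `agent`, `breaks`, `stim_fraction`, `seed`; any omitted section takes the
#' canonical default (a file containing only `seed: 7` is a complete
#' config). Validation failures name the offending field.
#'
#' @param path YAML file path.
#' @param config An `ats_experiment_config`.
#' @return `load_config()` returns a validated config; `save_config()` the
#'   path, invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("mouse_ids", "days", "schedule", "water",
                                   "stages", "agent", "breaks",
                                   "stim_fraction", "seed"))
  if (length(unknown) > 0) {
    stop("unknown config section: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sched_args <- raw$schedule %||% list()
  schedule <- do.call(schedule_config, sched_args)
  water <- if (is.null(raw$water)) water_config(schedule$mode) else
    do.call(water_config, raw$water)
  stage_tbl <- if (is.null(raw$stages)) stage_table() else
    stage_table_from_list(raw$stages)
  agent <- if (is.null(raw$agent)) agent_params() else
    do.call(agent_params, raw$agent)
  breaks <- lapply(raw$breaks %||% list(), function(b) do.call(break_spec, b))
  experiment_config(
    mouse_ids = as.character(raw$mouse_ids %||% c("m1", "m2")),
    days = raw$days %||% 7, schedule = schedule, water = water,
    stage_tbl = stage_tbl, agent = agent, breaks = breaks,
    stim_fraction = raw$stim_fraction %||% 0, seed = raw$seed %||% 1)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  st <- config$stage_tbl
  rows <- purrr::pmap(st, function(stage, light_on_s, limited_hold_s,
                                   iti_choices_s, reward_ul, min_correct,
                                   min_accuracy_pct, max_omission_pct) {
    row <- list(stage = as.integer(stage), light_on_s = light_on_s,
                limited_hold_s = limited_hold_s,
                iti_choices_s = as.list(iti_choices_s),
                reward_ul = reward_ul)
    if (!is.na(min_correct)) row$min_correct <- as.integer(min_correct)
    if (!is.na(min_accuracy_pct)) row$min_accuracy_pct <- min_accuracy_pct
    if (!is.na(max_omission_pct)) row$max_omission_pct <- max_omission_pct
    row
  })
  doc <- list(
    mouse_ids = as.list(config$mouse_ids), days = config$days,
    schedule = unclass(config$schedule), water = unclass(config$water),
    stages = rows,
    agent = list(
      entry_prob_by_hour = as.list(unname(config$agent$entry_prob_by_hour)),
      detect_floor = config$agent$detect_floor,
      detect_ceiling = config$agent$detect_ceiling,
      detect_halfpoint_s = config$agent$detect_halfpoint_s,
      skill = config$agent$skill, learning_rate = config$agent$learning_rate,
      premature_hazard_per_s = config$agent$premature_hazard_per_s,
      omission_prob = config$agent$omission_prob,
      rt_mu_log = config$agent$rt_mu_log,
      rt_sigma_log = config$agent$rt_sigma_log,
      wrong_port_prob = config$agent$wrong_port_prob),
    breaks = lapply(config$breaks, unclass),
    stim_fraction = config$stim_fraction, seed = config$seed)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Simulate an experiment from a configuration and write its logs
#'
#' Runs [run_experiment()] for the configured cohort and writes the trial
#' log, session index, gate events, water events and a run manifest into
#' `out_dir`. Identical config and seed produce byte-identical outputs.
#'
#' @param config An [experiment_config()] or path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return The `ats_experiment` object, invisibly.
#' @export
simulate_experiment <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  exp <- run_experiment(
    mouse_ids = config$mouse_ids, days = config$days,
    agents = virtual_mouse(config$agent), stage_tbl = config$stage_tbl,
    schedule = config$schedule, water = config$water, breaks = config$breaks,
    stim_fraction = config$stim_fraction, seed = config$seed)
  write_trial_log(exp$trials, file.path(out_dir, "trials.csv"))
  write_session_index(exp$sessions, file.path(out_dir, "sessions.csv"))
  readr::write_csv(exp$gate_events, file.path(out_dir, "gate_events.csv"),
                   na = "")
  if (nrow(exp$water_events) > 0) {
    readr::write_csv(exp$water_events, file.path(out_dir, "water_events.csv"),
                     na = "")
  }
  write_manifest(config, out_dir, t0)
  invisible(exp)
}

# Run manifest: config hash, seed, version, wall times, outputs. Written
# last so its presence marks a complete run.
write_manifest <- function(config, out_dir, t0) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ats5c")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Content hash of a config via its canonical YAML serialization.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  txt <- paste(readLines(tmp), collapse = "\n")
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Analyse a simulated (or imported) experiment directory
#'
#' Reads `trials.csv` and `sessions.csv` from `in_dir` and writes the
#' standard analysis tables to `out_dir`: `session_metrics.csv`,
#' `daily_metrics.csv`, `learning_curve.csv`, `activity_profile.csv` and
#' `stage_timeline.csv`.
#'
#' @param in_dir Directory holding simulation outputs.
#' @param out_dir Output directory for the analysis CSVs.
#' @return Named list of the five tibbles, invisibly.
#' @export
analyze_experiment <- function(in_dir, out_dir = in_dir) {
  trials <- read_trial_log(file.path(in_dir, "trials.csv"))
  sessions <- read_session_index(file.path(in_dir, "sessions.csv"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    session_metrics = session_metrics(trials),
    daily_metrics = daily_aggregate(trials),
    learning_curve = learning_curve(trials),
    activity_profile = entry_probability_by_hour(sessions),
    stage_timeline = stage_timeline(trials))
  for (name in names(out)) {
    readr::write_csv(out[[name]], file.path(out_dir, paste0(name, ".csv")),
                     na = "")
  }
  invisible(out)
}

#' Render a summary report for an analysed experiment
#'
#' Writes a plain-markdown report with five sections (overview, circadian
#' activity profile, learning curves, stage timeline, performance metrics)
#' plus the corresponding figures as PNG files. Deterministic given the
#' analysis inputs.
#'
#' @param in_dir Directory holding the analysis CSVs (from
#'   [analyze_experiment()]).
#' @param out_file Path of the markdown report; figures are placed next to
#'   it.
#' @return `out_file`, invisibly.
#' @export
report_experiment <- function(in_dir, out_file = file.path(in_dir, "report.md")) {
  need <- c("session_metrics.csv", "daily_metrics.csv", "learning_curve.csv",
            "activity_profile.csv", "stage_timeline.csv")
  have <- file.exists(file.path(in_dir, need))
  if (!all(have)) {
    stop("missing analysis inputs: ", paste(need[!have], collapse = ", "),
         call. = FALSE)
  }
  rd <- function(f) readr::read_csv(file.path(in_dir, f),
                                    show_col_types = FALSE, progress = FALSE)
  daily <- rd("daily_metrics.csv")
  curve <- rd("learning_curve.csv")
  activity <- rd("activity_profile.csv")
  timeline <- rd("stage_timeline.csv")
  sess <- rd("session_metrics.csv")

  fig_dir <- dirname(out_file)
  figs <- character()
  save_fig <- function(plot, name) {
    f <- file.path(fig_dir, name)
    ggplot2::ggsave(f, plot, width = 7, height = 4, dpi = 120)
    figs[[name]] <<- name
  }
  class(activity) <- c("ats_activity", class(activity))
  class(curve) <- c("ats_learning_curve", class(curve))
  if (nrow(activity) > 0) save_fig(plot_activity_profile(activity),
                                   "activity_profile.png")
  if (nrow(curve) > 0) save_fig(plot_learning_curve(curve),
                                "learning_curve.png")
  if (nrow(timeline) > 0) save_fig(plot_stage_timeline(timeline),
                                   "stage_timeline.png")

  fmt <- function(x) formatC(x, digits = 2, format = "f")
  lines <- c(
    "# Training experiment report", "",
    "## 1. Overview", "",
    sprintf("- Mice: %d", dplyr::n_distinct(sess$mouse_id)),
    sprintf("- Days with data: %d", dplyr::n_distinct(daily$day)),
    sprintf("- Sessions with trials: %d", nrow(sess)),
    sprintf("- Trials: %d", sum(sess$n_trials)), "",
    "## 2. Circadian activity profile", "",
    if ("activity_profile.png" %in% names(figs))
      "![activity](activity_profile.png)" else "(no activity data)", "",
    "## 3. Learning curves", "",
    if ("learning_curve.png" %in% names(figs))
      "![learning](learning_curve.png)" else "(fewer trials than one window)",
    "",
    "## 4. Stage timeline", "",
    if ("stage_timeline.png" %in% names(figs))
      "![stages](stage_timeline.png)" else "(no stage data)", "",
    "## 5. Performance metrics (daily means per mouse)", "",
    "| mouse | day | trials | accuracy % | premature % | omission % | RT (s) | stage |",
    "|---|---|---|---|---|---|---|---|")
  if (nrow(daily) > 0) {
    lines <- c(lines, sprintf(
      "| %s | %d | %d | %s | %s | %s | %s | %d |",
      daily$mouse_id, daily$day, daily$n_trials, fmt(daily$accuracy_pct),
      fmt(daily$premature_pct), fmt(daily$omission_pct), fmt(daily$mean_rt_s),
      daily$stage_reached))
  }
  writeLines(lines, out_file)
  invisible(out_file)
}
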