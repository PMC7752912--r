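#' The 12-stage 5CSRTT difficulty ladder
#'
#' Training difficulty in the 5-choice serial reaction time task is set by the
#' duration of the light cue ("light on") and the extra response window after
#' the cue extinguishes (the limited hold, LH). The canonical protocol uses 12
#' stages of progressively shorter cues; a mouse advances to the next stage as
#' soon as its running performance since the last advancement passes that
#' stage's entry criteria.
#'
#' `stage_table()` returns the canonical ladder as a tibble with one row per
#' stage:
#' \describe{
#'   \item{stage}{stage index, 1--12}
#'   \item{light_on_s}{cue duration in seconds: 30, 20, 10, 5, 2.5, 1.25, 1,
#'     0.9, 0.8, 0.7, 0.6, 0.5}
#'   \item{limited_hold_s}{limited hold in seconds: 30, 20, 10, then 5 for all
#'     later stages, so every stage offers at least 5 s to respond}
#'   \item{iti_choices_s}{list-column of permitted inter-trial-interval
#'     durations; a fixed 5 s for stages 1--2, randomized among 3, 4 and 5 s
#'     from stage 3 onward}
#'   \item{reward_ul}{water reward per correct trial: 6 ul at stage 1, 5 ul at
#'     stage 2, 4 ul afterwards}
#'   \item{min_correct, min_accuracy_pct, max_omission_pct}{criteria to enter
#'     the stage (NA when not applicable): stage 2 needs >= 30 correct;
#'     stage 3 >= 50 correct; stages 4--5 additionally > 80 percent accuracy
#'     (strict); stages 6--12 additionally < 20 percent omissions (strict)}
#' }
#'
#' @return A validated 12-row tibble of class `ats_stage_table`.
#' @seealso [criteria_met()], [sample_iti()], [reward_volume()]
#' @export
#' @examples
#' stage_table()
stage_table <- function() {
  tbl <- tibble::tibble(
    stage = 1:12,
    light_on_s = c(30, 20, 10, 5, 2.5, 1.25, 1, 0.9, 0.8, 0.7, 0.6, 0.5),
    limited_hold_s = c(30, 20, 10, rep(5, 9)),
    iti_choices_s = c(list(5), list(5), rep(list(c(3, 4, 5)), 10)),
    reward_ul = c(6, 5, rep(4, 10)),
    min_correct = c(NA, 30, rep(50, 10)),
    min_accuracy_pct = c(NA, NA, NA, rep(80, 9)),
    max_omission_pct = c(rep(NA, 5), rep(20, 7))
  )
  validate_stage_table(tbl)
}

#' Validate a stage table
#'
#' Checks the structural invariants of a 12-stage ladder: contiguous stage
#' indices 1..12, a non-increasing cue duration, a response window
#' (`light_on_s + limited_hold_s`) of at least 5 s at every stage, rewards
#' restricted to 6, 5 or 4 ul, non-empty ITI menus, percent criteria in
#' \[0, 100\], and at least one advancement criterion for every stage >= 2.
#'
#' @param tbl A data frame shaped like [stage_table()].
#' @return `tbl` as an `ats_stage_table` tibble, invisibly usable downstream.
#' @export
validate_stage_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("stage", "light_on_s", "limited_hold_s", "iti_choices_s",
            "reward_ul", "min_correct", "min_accuracy_pct", "max_omission_pct")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    stop("stage table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tbl) != 12 || !identical(as.integer(tbl$stage), 1:12)) {
    stop("stage table must have exactly 12 stages indexed 1..12; got stages ",
         paste(tbl$stage, collapse = ","), call. = FALSE)
  }
  if (any(diff(tbl$light_on_s) > 0)) {
    stop("light_on_s must be non-increasing across stages", call. = FALSE)
  }
  window <- tbl$light_on_s + tbl$limited_hold_s
  if (any(window < 5)) {
    stop("every stage must allow at least 5 s to respond ",
         "(light_on_s + limited_hold_s >= 5); violated at stage ",
         paste(tbl$stage[window < 5], collapse = ","), call. = FALSE)
  }
  if (!all(tbl$reward_ul %in% c(6, 5, 4))) {
    stop("reward_ul must be one of 6, 5, 4 ul", call. = FALSE)
  }
  if (any(lengths(tbl$iti_choices_s) == 0)) {
    stop("iti_choices_s must be non-empty for every stage", call. = FALSE)
  }
  pct <- c(tbl$min_accuracy_pct, tbl$max_omission_pct)
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop("percent criteria must lie in [0, 100]", call. = FALSE)
  }
  if (any(tbl$min_correct < 0, na.rm = TRUE)) {
    stop("min_correct must be nonnegative", call. = FALSE)
  }
  has_criterion <- !is.na(tbl$min_correct) | !is.na(tbl$min_accuracy_pct) |
    !is.na(tbl$max_omission_pct)
  if (any(!has_criterion[-1])) {
    stop("stages >= 2 must set at least one advancement criterion; missing at ",
         "stage ", paste(tbl$stage[-1][!has_criterion[-1]], collapse = ","),
         call. = FALSE)
  }
  class(tbl) <- c("ats_stage_table", class(tbl))
  tbl
}

#' Fresh per-stage performance counters
#'
#' Running totals of trial outcomes accumulated since the last stage
#' advancement; advancement criteria are evaluated against these after every
#' completed trial, and they reset to zero when the mouse moves up a stage.
#'
#' @return A named list with `correct`, `incorrect`, `omitted`, `premature`,
#'   all zero.
#' @export
new_counters <- function() {
  list(correct = 0L, incorrect = 0L, omitted = 0L, premature = 0L)
}

#' Decide whether stage-entry criteria are satisfied
#'
#' A stage's entry criteria combine up to three thresholds: a minimum number
#' of correct responses (`correct >= min_correct`), a strict accuracy floor
#' (`accuracy > min_accuracy_pct`, accuracy = correct / (correct + incorrect)
#' x 100) and a strict omission ceiling (`omission < max_omission_pct`,
#' omission = omitted / (correct + incorrect + omitted) x 100; premature
#' trials are excluded from both denominators). All thresholds that are set
#' must hold simultaneously. A percent comparison whose denominator is zero
#' counts as not met.
#'
#' @param criteria One stage-table row (as a list or one-row data frame) with
#'   `min_correct`, `min_accuracy_pct`, `max_omission_pct`; NA disables a
#'   threshold.
#' @param counters Counters as returned by [new_counters()] and updated by the
#'   session engine.
#' @return `TRUE` if every set threshold holds.
#' @export
#' @examples
#' st <- stage_table()
#' criteria_met(st[2, ], list(correct = 30, incorrect = 0,
#'                            omitted = 0, premature = 0))
criteria_met <- function(criteria, counters) {
  stopifnot(all(c("correct", "incorrect", "omitted", "premature") %in%
                  names(counters)))
  if (any(unlist(counters[c("correct", "incorrect", "omitted", "premature")]) < 0)) {
    stop("counters must be nonnegative", call. = FALSE)
  }
  min_correct <- as.numeric(criteria[["min_correct"]])
  min_acc <- as.numeric(criteria[["min_accuracy_pct"]])
  max_om <- as.numeric(criteria[["max_omission_pct"]])

  if (!is.na(min_correct) && counters$correct < min_correct) return(FALSE)
  if (!is.na(min_acc)) {
    denom <- counters$correct + counters$incorrect
    if (denom == 0) return(FALSE)
    if (!(100 * counters$correct / denom > min_acc)) return(FALSE)
  }
  if (!is.na(max_om)) {
    denom <- counters$correct + counters$incorrect + counters$omitted
    if (denom == 0) return(FALSE)
    if (!(100 * counters$omitted / denom < max_om)) return(FALSE)
  }
  TRUE
}

#' Water reward volume for a stage
#'
#' 6 ul at stage 1, 5 ul at stage 2 and 4 ul at every later stage.
#'
#' @param stage_index Integer stage index, 1--12.
#' @return Reward volume in microliters.
#' @export
reward_volume <- function(stage_index) {
  if (any(stage_index < 1 | stage_index > 12)) {
    stop("stage_index must lie in 1..12", call. = FALSE)
  }
  c(6, 5, rep(4, 10))[stage_index]
}

#' Draw an inter-trial interval for a stage
#'
#' Uniform draw from the stage's ITI menu (`iti_choices_s`): always 5 s in
#' stages 1--2, one of 3, 4 or 5 s from stage 3 onward.
#'
#' @param stage One row of a stage table (one-row data frame or list with an
#'   `iti_choices_s` entry).
#' @return ITI duration in seconds.
#' @export
sample_iti <- function(stage) {
  choices <- stage[["iti_choices_s"]]
  if (is.list(choices)) choices <- choices[[1]]
  if (length(choices) == 1) return(choices)
  choices[sample.int(length(choices), 1L)]
}

#' Write / read a stage table as YAML
#'
#' The ladder serializes as a 12-element sequence of mappings with keys
#' `stage`, `light_on_s`, `limited_hold_s`, `iti_choices_s`, `reward_ul`,
#' `min_correct`, `min_accuracy_pct`, `max_omission_pct` (criteria absent when
#' unset). [stage_table()] round-trips through this format exactly.
#'
#' @param tbl A stage table.
#' @param path File path.
#' @return `write_stage_table()` returns `path` invisibly;
#'   `read_stage_table()` returns a validated `ats_stage_table`.
#' @export
write_stage_table <- function(tbl, path) {
  tbl <- validate_stage_table(tbl)
  rows <- purrr::pmap(tbl, function(stage, light_on_s, limited_hold_s,
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
  yaml::write_yaml(rows, path, precision = 15)
  invisible(path)
}

#' @rdname write_stage_table
#' @export
read_stage_table <- function(path) {
  rows <- yaml::read_yaml(path)
  stage_table_from_list(rows)
}

# Build a validated stage table from a list of per-stage mappings (YAML form).
stage_table_from_list <- function(rows) {
  tbl <- purrr::map_dfr(rows, function(row) {
    tibble::tibble(
      stage = as.integer(row$stage),
      light_on_s = as.numeric(row$light_on_s),
      limited_hold_s = as.numeric(row$limited_hold_s),
      iti_choices_s = list(as.numeric(unlist(row$iti_choices_s))),
      reward_ul = as.numeric(row$reward_ul),
      min_correct = if (is.null(row$min_correct)) NA_real_ else as.numeric(row$min_correct),
      min_accuracy_pct = if (is.null(row$min_accuracy_pct)) NA_real_ else as.numeric(row$min_accuracy_pct),
      max_omission_pct = if (is.null(row$max_omission_pct)) NA_real_ else as.numeric(row$max_omission_pct)
    )
  })
  validate_stage_table(tbl)
}
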