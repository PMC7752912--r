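#' Plot the circadian activity profile
#'
#' Bar chart of entry probability by hour of day, with the light phase
#' (07:00--19:00) shaded.
#'
#' @param profile An activity profile from [entry_probability_by_hour()].
#' @param lights_on_hour,lights_off_hour Light-phase boundaries for shading.
#' @return A ggplot.
#' @export
plot_activity_profile <- function(profile, lights_on_hour = 7,
                                  lights_off_hour = 19) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$hour,
                                        y = .data$entry_probability)) +
    ggplot2::annotate("rect", xmin = lights_on_hour - 0.5,
                      xmax = lights_off_hour - 0.5, ymin = -Inf, ymax = Inf,
                      fill = "lightyellow", alpha = 0.6) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "hour of day", y = "entry probability",
                  title = "Voluntary session entries by hour") +
    ggplot2::theme_minimal()
}

#' Plot sliding-window learning curves
#'
#' @param curve A learning curve from [learning_curve()].
#' @param metric Metric column to plot (default accuracy).
#' @return A ggplot, one line per mouse.
#' @export
plot_learning_curve <- function(curve, metric = "accuracy_pct") {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$trial_mid,
                                      y = .data[[metric]],
                                      colour = .data$mouse_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial (window centre)", y = metric,
                  title = "Learning curve over completed trials",
                  colour = "mouse") +
    ggplot2::theme_minimal()
}

#' Plot per-day stage progression
#'
#' @param timeline A tibble from [stage_timeline()].
#' @return A ggplot step plot, one line per mouse.
#' @export
plot_stage_timeline <- function(timeline) {
  ggplot2::ggplot(timeline, ggplot2::aes(x = .data$day, y = .data$stage_end,
                                         colour = .data$mouse_id)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(breaks = 1:12, limits = c(1, 12)) +
    ggplot2::labs(x = "experiment day", y = "stage reached",
                  title = "Stage progression", colour = "mouse") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @method autoplot ats_activity
#' @export
autoplot.ats_activity <- function(object, ...) plot_activity_profile(object, ...)

#' @method autoplot ats_learning_curve
#' @export
autoplot.ats_learning_curve <- function(object, ...) plot_learning_curve(object, ...)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an experiment into per-session metrics
#'
#' @param x An `ats_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble of per-session performance metrics.
#' @method tidy ats_experiment
#' @export
tidy.ats_experiment <- function(x, ...) {
  session_metrics(x$trials)
}

#' One-row experiment summary
#'
#' @param x An `ats_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: cohort size, days, sessions offered/entered,
#'   trials, mean trials per mouse-day with data, overall metrics, and the
#'   mean final stage.
#' @method glance ats_experiment
#' @export
glance.ats_experiment <- function(x, ...) {
  overall <- compute_metrics(x$trials)
  daily <- daily_aggregate(x$trials)
  tibble::tibble(
    n_mice = length(x$final_states),
    n_sessions_offered = nrow(x$sessions),
    n_sessions_entered = sum(x$sessions$entered),
    n_trials = nrow(x$trials),
    trials_per_mouse_day = if (nrow(daily) > 0) mean(daily$n_trials) else NA_real_,
    accuracy_pct = overall$accuracy_pct,
    premature_pct = overall$premature_pct,
    omission_pct = overall$omission_pct,
    mean_rt_s = overall$mean_rt_s,
    mean_final_stage = mean(vapply(x$final_states, `[[`, integer(1), "stage"))
  )
}
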