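#' Default circadian entry-probability curve
#'
#' Probability, per scheduled gate opening, that the mouse enters the
#' training chamber, indexed by hour of day (0--23). Mice on a 12-h
#' light-dark cycle (lights on 07:00) engage readily at night, disengage
#' through the middle of the light phase with a minimum in the 15:00 hour,
#' and recover towards the end of the day. The default curve holds 0.9
#' through the night and early morning, declines linearly from 09:00 to 0.52
#' at 15:00, and rises linearly back to 0.94 at 23:00.
#'
#' @return Numeric vector of 24 probabilities, named "0".."23".
#' @export
default_circadian_curve <- function() {
  p <- numeric(24)
  p[1:9] <- 0.9                                    # hours 0..8
  p[10:16] <- 0.9 + (0.52 - 0.9) * (1:7) / 7       # hours 9..15, dip to 0.52
  p[17:24] <- 0.52 + (0.94 - 0.52) * (1:8) / 8     # hours 16..23, recovery
  names(p) <- as.character(0:23)
  p
}

#' Virtual-mouse agent parameters
#'
#' The virtual mouse is a generative stand-in for a real animal: it decides
#' whether to enter scheduled sessions (circadian curve), whether it pokes
#' early (exponential premature hazard during the ITI), whether it detects
#' the cue (a saturating psychometric in cue duration, scaled by a learned
#' skill), where and when it pokes (wrong-port probability, lognormal
#' reaction times), and whether it omits. None of this claims biological
#' realism; the functional forms are the simplest ones producing the
#' qualitative phenomena of interest (circadian dip, cue-duration-limited
#' detection, trial-driven learning curves, premature and omission rates,
#' sub-second reaction times).
#'
#' Detection probability for a cue of duration `d` at skill `s` is
#' `detect_floor + (detect_ceiling - detect_floor) * s * d / (d + detect_halfpoint_s)`.
#'
#' @param entry_prob_by_hour 24 entry probabilities, default
#'   [default_circadian_curve()].
#' @param detect_floor,detect_ceiling Detection probability bounds.
#' @param detect_halfpoint_s Cue duration (s) at which the duration factor
#'   reaches one half.
#' @param skill Current skill in \[0, 1\].
#' @param learning_rate Skill gain per completed trial.
#' @param premature_hazard_per_s Constant hazard (s^-1) of an impulsive poke
#'   during the ITI.
#' @param omission_prob Probability of not responding when the cue goes
#'   undetected.
#' @param rt_mu_log,rt_sigma_log Lognormal reaction-time parameters
#'   (log-seconds); the defaults give a mean near 0.83 s.
#' @param wrong_port_prob Probability that a detected cue is answered at a
#'   non-cued port.
#' @return A list of class `ats_agent_params`.
#' @export
agent_params <- function(entry_prob_by_hour = default_circadian_curve(),
                         detect_floor = 0.1, detect_ceiling = 0.98,
                         detect_halfpoint_s = 0.5, skill = 0.2,
                         learning_rate = 0.001,
                         premature_hazard_per_s = 0.02, omission_prob = 0.4,
                         rt_mu_log = -0.25, rt_sigma_log = 0.35,
                         wrong_port_prob = 0.1) {
  p <- list(entry_prob_by_hour = entry_prob_by_hour,
            detect_floor = detect_floor, detect_ceiling = detect_ceiling,
            detect_halfpoint_s = detect_halfpoint_s, skill = skill,
            learning_rate = learning_rate,
            premature_hazard_per_s = premature_hazard_per_s,
            omission_prob = omission_prob, rt_mu_log = rt_mu_log,
            rt_sigma_log = rt_sigma_log, wrong_port_prob = wrong_port_prob)
  validate_agent_params(p)
}

validate_agent_params <- function(p) {
  p$entry_prob_by_hour <- stats::setNames(
    as.numeric(unlist(p$entry_prob_by_hour)), as.character(0:23))
  probs <- c(p$entry_prob_by_hour, p$detect_floor, p$detect_ceiling, p$skill,
             p$omission_prob, p$wrong_port_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("agent probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(p$entry_prob_by_hour) != 24) {
    stop("entry_prob_by_hour must have 24 entries", call. = FALSE)
  }
  if (p$premature_hazard_per_s < 0) {
    stop("premature_hazard_per_s must be nonnegative", call. = FALSE)
  }
  if (p$rt_sigma_log <= 0) stop("rt_sigma_log must be positive", call. = FALSE)
  class(p) <- c("ats_agent_params", "list")
  p
}

#' Decide whether the mouse enters a scheduled session
#'
#' A Bernoulli draw with the hour's entry probability.
#'
#' @param hour Hour of day, 0--23.
#' @param params Agent parameters.
#' @return Logical.
#' @export
entry_decision <- function(hour, params) {
  stats::runif(1) < params$entry_prob_by_hour[[hour + 1L]]
}

#' Cue-detection probability
#'
#' Saturating psychometric in cue duration, scaled by skill:
#' `floor + (ceiling - floor) * skill * d / (d + halfpoint)`. Monotone
#' increasing in both cue duration and skill.
#'
#' @param light_on_s Cue duration in seconds.
#' @param params Agent parameters.
#' @return Detection probability.
#' @export
detect_prob <- function(light_on_s, params) {
  params$detect_floor + (params$detect_ceiling - params$detect_floor) *
    params$skill * light_on_s / (light_on_s + params$detect_halfpoint_s)
}

#' Generate the virtual mouse's response for one trial
#'
#' The generative sequence mirrors the trial phases: (1) an impulsive poke
#' time is drawn from an exponential with rate `premature_hazard_per_s` and
#' accepted if it falls inside the ITI; (2) otherwise the cue is detected
#' with probability [detect_prob()], and a detected cue is answered after a
#' lognormal reaction time (truncated to the response window) at the cued
#' port with probability `1 - wrong_port_prob`, else at a uniformly random
#' other port; (3) an undetected cue is omitted with probability
#' `omission_prob`, or answered with a late poke at a uniformly random port
#' at a uniform time within the window.
#'
#' @param stage_row One stage-table row (list or one-row data frame).
#' @param iti_s ITI duration for this trial.
#' @param cue_port Cued port (the agent can only exploit this once it
#'   detects the cue).
#' @param params Agent parameters.
#' @return A response list with `poke_time_s` and `poke_port` (both NA for no
#'   poke).
#' @export
plan_trial_response <- function(stage_row, iti_s, cue_port, params) {
  window_s <- stage_row$light_on_s + stage_row$limited_hold_s
  if (params$premature_hazard_per_s > 0) {
    t_imp <- stats::rexp(1, rate = params$premature_hazard_per_s)
    if (t_imp < iti_s) {
      return(list(poke_time_s = t_imp, poke_port = sample.int(5L, 1L)))
    }
  }
  if (stats::runif(1) < detect_prob(stage_row$light_on_s, params)) {
    rt <- stats::rlnorm(1, params$rt_mu_log, params$rt_sigma_log)
    for (i in 1:100) {
      if (rt <= window_s) break
      rt <- stats::rlnorm(1, params$rt_mu_log, params$rt_sigma_log)
    }
    if (rt > window_s) rt <- stats::runif(1, 0, window_s)
    port <- if (stats::runif(1) < params$wrong_port_prob) {
      sample(setdiff(1:5, cue_port), 1L)
    } else {
      cue_port
    }
    return(list(poke_time_s = iti_s + rt, poke_port = port))
  }
  if (stats::runif(1) < params$omission_prob) {
    return(list(poke_time_s = NA_real_, poke_port = NA_integer_))
  }
  list(poke_time_s = iti_s + stats::runif(1, 0, window_s),
       poke_port = sample.int(5L, 1L))
}

#' Update skill after a completed trial
#'
#' Skill grows by `learning_rate` per completed trial, capped at 1. By
#' default the update is outcome-independent (any completed trial teaches);
#' set `reward_gated = TRUE` to restrict learning to correct trials.
#'
#' @param params Agent parameters.
#' @param outcome Trial outcome string.
#' @param reward_gated Learn only from correct trials?
#' @return Updated parameters.
#' @export
update_skill <- function(params, outcome = "correct", reward_gated = FALSE) {
  if (!reward_gated || identical(outcome, "correct")) {
    params$skill <- min(1, params$skill + params$learning_rate)
  }
  params
}

#' Named agent perturbations
#'
#' A perturbation is a temporary shift of agent parameters used to emulate
#' experimental manipulations:
#' \describe{
#'   \item{scopolamine_like}{muscarinic-antagonist-like impairment: accuracy
#'     drops (wrong-port probability rises) and impulsivity rises (premature
#'     hazard increases) for the stated number of sessions}
#'   \item{stim_learning_delay}{slowed learning under pre-cue
#'     photostimulation: learning rate multiplied by a factor < 1}
#'   \item{post_break_lapse}{transient post-break lapse: mild accuracy drop,
#'     more prematures and omissions for a few sessions}
#' }
#'
#' `accuracy_delta` is in percentage points and is applied to the wrong-port
#' probability as `wrong_port_prob - accuracy_delta / 100` (a delta of -10
#' raises the wrong-port probability by 0.10); `premature_delta` is a hazard
#' delta in s^-1; `omission_delta` a probability delta;
#' `learning_rate_factor` multiplies the learning rate. Perturbed parameters
#' are clipped to their valid ranges.
#'
#' @param name One of `"scopolamine_like"`, `"stim_learning_delay"`,
#'   `"post_break_lapse"`.
#' @param accuracy_delta,premature_delta,omission_delta,learning_rate_factor
#'   Override the named preset's adjustments.
#' @param duration_sessions How many entered sessions the perturbation lasts.
#' @return A list of class `ats_perturbation`.
#' @export
perturbation_spec <- function(name = c("scopolamine_like",
                                       "stim_learning_delay",
                                       "post_break_lapse"),
                              accuracy_delta = NULL, premature_delta = NULL,
                              omission_delta = NULL,
                              learning_rate_factor = NULL,
                              duration_sessions = 1L) {
  name <- match.arg(name)
  preset <- switch(name,
    scopolamine_like = list(accuracy_delta = -25, premature_delta = 0.05,
                            omission_delta = 0, learning_rate_factor = 1),
    stim_learning_delay = list(accuracy_delta = 0, premature_delta = 0,
                               omission_delta = 0, learning_rate_factor = 0.5),
    post_break_lapse = list(accuracy_delta = -10, premature_delta = 0.02,
                            omission_delta = 0.1, learning_rate_factor = 1)
  )
  spec <- list(
    name = name,
    accuracy_delta = accuracy_delta %||% preset$accuracy_delta,
    premature_delta = premature_delta %||% preset$premature_delta,
    omission_delta = omission_delta %||% preset$omission_delta,
    learning_rate_factor = learning_rate_factor %||% preset$learning_rate_factor,
    duration_sessions = as.integer(duration_sessions)
  )
  class(spec) <- c("ats_perturbation", "list")
  spec
}

#' Apply a perturbation to agent parameters
#'
#' Returns an adjusted copy (the input is untouched) carrying the baseline
#' parameters and a session countdown, so [tick_perturbation()] can restore
#' the baseline when the perturbation expires.
#'
#' @param params Agent parameters.
#' @param spec A [perturbation_spec()].
#' @return Perturbed parameters.
#' @export
apply_perturbation <- function(params, spec) {
  if (!inherits(spec, "ats_perturbation")) {
    stop("unknown perturbation: pass a perturbation_spec()", call. = FALSE)
  }
  baseline <- params
  params$wrong_port_prob <- clip01(params$wrong_port_prob -
                                     spec$accuracy_delta / 100)
  params$premature_hazard_per_s <- max(0, params$premature_hazard_per_s +
                                         spec$premature_delta)
  params$omission_prob <- clip01(params$omission_prob + spec$omission_delta)
  params$learning_rate <- params$learning_rate * spec$learning_rate_factor
  attr(params, "baseline") <- baseline
  attr(params, "sessions_remaining") <- spec$duration_sessions
  params
}

#' Advance the perturbation countdown by one entered session
#'
#' Decrements the remaining-session counter of an active perturbation and
#' restores the baseline parameters once it reaches zero (the learned skill
#' is carried over).
#'
#' @param params Agent parameters (possibly perturbed).
#' @return Parameters for the next session.
#' @export
tick_perturbation <- function(params) {
  remaining <- attr(params, "sessions_remaining")
  if (is.null(remaining)) return(params)
  remaining <- remaining - 1L
  if (remaining <= 0L) {
    baseline <- attr(params, "baseline")
    baseline$skill <- params$skill
    return(baseline)
  }
  attr(params, "sessions_remaining") <- remaining
  params
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Construct a stochastic virtual-mouse agent
#'
#' Wraps [agent_params()] into the agent interface the engine consumes: a
#' `respond(stage_row, iti_s, cue_port, params)` function, an
#' `entry_prob(hour, params)` function, and a `learns` flag enabling the
#' per-trial skill update.
#'
#' @param params Agent parameters.
#' @return A list of class `ats_agent`.
#' @export
virtual_mouse <- function(params = agent_params()) {
  structure(list(
    kind = "virtual_mouse",
    params = params,
    learns = TRUE,
    respond = function(stage_row, iti_s, cue_port, params) {
      plan_trial_response(stage_row, iti_s, cue_port, params)
    },
    entry_prob = function(hour, params) params$entry_prob_by_hour[[hour + 1L]]
  ), class = "ats_agent")
}

#' Scripted deterministic agents
#'
#' Test fixtures implementing fixed policies against any stage:
#' \describe{
#'   \item{always_correct}{pokes the cued port 0.5 s after cue onset}
#'   \item{never_poke}{omits every trial}
#'   \item{always_premature}{pokes port 1 halfway through the ITI}
#'   \item{fixed_accuracy}{pokes 1 s after cue onset, at the cued port with
#'     probability `p`, else a random other port (seeded, not deterministic)}
#' }
#' Scripted agents always enter sessions and do not learn.
#'
#' @param policy Policy name.
#' @param p Target accuracy for `fixed_accuracy`.
#' @return A list of class `ats_agent`.
#' @export
scripted_agent <- function(policy = c("always_correct", "never_poke",
                                      "always_premature", "fixed_accuracy"),
                           p = 0.8) {
  policy <- match.arg(policy)
  respond <- switch(policy,
    always_correct = function(stage_row, iti_s, cue_port, params) {
      list(poke_time_s = iti_s + 0.5, poke_port = cue_port)
    },
    never_poke = function(stage_row, iti_s, cue_port, params) {
      list(poke_time_s = NA_real_, poke_port = NA_integer_)
    },
    always_premature = function(stage_row, iti_s, cue_port, params) {
      list(poke_time_s = iti_s / 2, poke_port = 1L)
    },
    fixed_accuracy = function(stage_row, iti_s, cue_port, params) {
      port <- if (stats::runif(1) < p) cue_port else sample(setdiff(1:5, cue_port), 1L)
      list(poke_time_s = iti_s + 1, poke_port = port)
    }
  )
  structure(list(
    kind = paste0("scripted_", policy),
    params = NULL,
    learns = FALSE,
    respond = respond,
    entry_prob = function(hour, params) 1
  ), class = "ats_agent")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
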