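#' Expected latency and engagement probability on a given training day
#'
#' The agent's expected action latency decays exponentially towards its
#' asymptote, `latency(day) = asymptote + (init - asymptote) *
#' exp(-(day - 1) / tau)`, and the engagement probability rises towards its
#' final value on the same exponential schedule. Both are monotone in day.
#'
#' @param agent An [agent_config()].
#' @param day Training day, 1-based.
#' @return A list with elements `expected_latency_s` and `engage_prob`.
#' @export
learning_schedule <- function(agent, day) {
  stopifnot(inherits(agent, "agent_config"))
  if (any(day < 1)) stop("day must be >= 1", call. = FALSE)
  if (agent$learning_tau_days <= 0)
    stop("learning_tau_days must be > 0", call. = FALSE)
  decay <- exp(-(day - 1) / agent$learning_tau_days)
  list(expected_latency_s = agent$latency_asymptote_s +
         (agent$latency_init_s - agent$latency_asymptote_s) * decay,
       engage_prob = agent$engage_prob_final +
         (agent$engage_prob_init - agent$engage_prob_final) * decay)
}

new_event_log <- function(events, mouse, phase, day, test) {
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(meta = list(mouse = mouse, phase = phase,
                             day = as.integer(day), test = as.integer(test)),
                 events = events),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> mouse=%s phase=%s day=%d test=%d: %d events\n",
              x$meta$mouse, x$meta$phase, x$meta$day, x$meta$test,
              nrow(x$events)))
  invisible(x)
}

event_row <- function(time_s, event, value = NA_real_) {
  data.frame(time_s = round(time_s, 4L), event = event, value = value,
             stringsAsFactors = FALSE)
}

# One lick bout as a regular train, truncated to [start, cap).
bout_licks <- function(start, rate_hz, duration_s, cap) {
  t <- seq(start, start + duration_s, by = 1 / rate_hz)
  t[t < cap]
}

#' Simulate one session of the operant task
#'
#' Runs the phase's task state machine with a virtual mouse and returns both
#' the behavioral event log and a ground-truth record of the agent's
#' latencies, trial outcomes and the times at which calcium transients
#' should later be injected by [generate_photometry()].
#'
#' Contingencies: in Phase I every lick while the tone is on triggers a
#' reward; in Phase II the first lever press outside an open trial starts a
#' 10 s trial and makes the spout available for `reward_window_s`; in Phase
#' III only a press inside the 5 s tone opens the spout.
#'
#' @param task A [task_config()].
#' @param agent An [agent_config()].
#' @param day Training day within `1..task$days`.
#' @param test_index Test index within the day (1-based).
#' @param mouse Mouse identifier written into the session metadata.
#' @param seed Session seed; defaults to a stream derived from
#'   `agent$rng_seed` and the (phase, day, test) coordinates.
#' @return A list with elements `log` (an `event_log`) and `truth` (a
#'   `sim_truth` with per-trial latencies/outcomes and transient times).
#' @export
run_task_state_machine <- function(task, agent, day, test_index = 1L,
                                   mouse = "m01", seed = NULL) {
  stopifnot(inherits(task, "task_config"), inherits(agent, "agent_config"))
  if (day < 1 || day > task$days)
    stop("day must lie within 1..task$days", call. = FALSE)
  if (is.null(seed))
    seed <- session_seed(agent$rng_seed, task$phase, day, test_index)
  set.seed(seed)

  sched <- learning_schedule(agent, day)
  out <- switch(task$phase,
                I = sim_phase_cued(task, agent, sched, press_required = FALSE),
                II = sim_phase_operant(task, agent, sched),
                III = sim_phase_cued(task, agent, sched, press_required = TRUE))

  log <- new_event_log(out$events, mouse, task$phase, day, test_index)
  truth <- structure(list(trials = out$trials,
                          transients = out$transients,
                          meta = log$meta, seed = seed),
                     class = "sim_truth")
  list(log = log, truth = truth)
}

# Phases I and III share the tone-driven trial schedule; Phase III
# additionally requires a lever press inside the tone to open the spout.
sim_phase_cued <- function(task, agent, sched, press_required) {
  n_range <- seq(task$trials_per_test[1], task$trials_per_test[2])
  n_trials <- if (length(n_range) == 1L) n_range else sample(n_range, 1L)
  period <- task$tone_duration_s + task$intertrial_interval_s
  ev <- list(event_row(0, "sync"))
  if (!press_required) ev <- c(ev, list(event_row(0.1, "spout_in")))
  trials <- vector("list", n_trials)
  trans <- list()
  t0 <- 5
  for (i in seq_len(n_trials)) {
    tone_on <- t0 + (i - 1) * period
    tone_off <- tone_on + task$tone_duration_s
    span_end <- tone_on + period
    ev <- c(ev, list(event_row(tone_on, "tone_on"),
                     event_row(tone_off, "tone_off")))
    engaged <- stats::runif(1) < sched$engage_prob
    latency <- NA_real_
    press_t <- NA_real_
    licks <- numeric(0)
    reward_open <- c(NA_real_, NA_real_)
    if (engaged) {
      latency <- rlnorm_mean(1, sched$expected_latency_s, agent$latency_cv)
      if (latency >= period - 0.5) latency <- NA_real_  # action missed trial
    }
    if (press_required) {
      if (!is.na(latency)) {
        press_t <- round(tone_on + latency, 4L)
        force <- stats::runif(1, agent$press_force_range[1],
                              agent$press_force_range[2])
        ev <- c(ev, list(event_row(press_t, "lever_press", round(force, 2L))))
        if (press_t >= tone_on && press_t < tone_off) {
          reward_open <- c(press_t, press_t + task$reward_window_s)
          ev <- c(ev, list(event_row(press_t, "spout_in"),
                           event_row(min(reward_open[2], span_end - 1e-3),
                                     "spout_out")))
        }
        lick_start <- press_t +
          rlnorm_mean(1, agent$press_to_lick_latency_s, agent$latency_cv)
        if (lick_start < span_end - 0.3 &&
            (!is.na(reward_open[1]) || stats::runif(1) < 0.5)) {
          licks <- bout_licks(lick_start, agent$lick_rate_hz,
                              agent$bout_duration_s, span_end - 0.1)
        }
      }
    } else {
      bout_start <- NA_real_
      if (!is.na(latency)) {
        bout_start <- tone_on + latency
      } else if (stats::runif(1) < agent$stray_lick_prob) {
        # off-cue bout during the intertrial interval
        bout_start <- tone_off +
          stats::runif(1, 0.5, task$intertrial_interval_s -
                         agent$bout_duration_s - 0.5)
        latency <- bout_start - tone_on
      }
      if (!is.na(bout_start))
        licks <- bout_licks(bout_start, agent$lick_rate_hz,
                            agent$bout_duration_s, span_end - 0.1)
      reward_open <- c(tone_on, tone_off)  # Phase I: spout live during tone
    }
    licks <- round(licks, 4L)
    rewarded <- if (length(licks) && !is.na(reward_open[1])) {
      licks >= reward_open[1] & licks < reward_open[2]
    } else rep(FALSE, length(licks))
    for (k in seq_along(licks)) {
      ev <- c(ev, list(event_row(licks[k], "lick")))
      if (rewarded[k])
        ev <- c(ev, list(event_row(licks[k], "reward_delivery", 2)))
    }
    outcome <- if (press_required && is.na(press_t)) "no_presses"
      else if (any(rewarded)) "rewarded"
      else if (length(licks)) "non_rewarded"
      else if (press_required) "non_rewarded"
      else "no_licks"
    trials[[i]] <- data.frame(trial_idx = i, latency_s = latency,
                              outcome = outcome, stringsAsFactors = FALSE)
    if (!is.na(press_t))
      trans <- c(trans, list(data.frame(
        time_s = press_t, linked_behavior = "lever_press", trial_idx = i,
        rewarded = any(rewarded), lick_end_s = NA_real_)))
    if (length(licks))
      trans <- c(trans, list(data.frame(
        time_s = licks[1], linked_behavior = "lick_bout_onset", trial_idx = i,
        rewarded = any(rewarded), lick_end_s = licks[length(licks)])))
  }
  collect_session(ev, trials, trans)
}

sim_phase_operant <- function(task, agent, sched) {
  ev <- list(event_row(0, "sync"))
  trials <- list()
  trans <- list()
  t_now <- rlnorm_mean(1, sched$expected_latency_s, agent$latency_cv)
  i <- 0L
  while (t_now < task$test_duration_s - 0.5) {
    i <- i + 1L
    press_t <- round(t_now, 4L)
    span_end <- press_t + task$trial_duration_s
    force <- stats::runif(1, agent$press_force_range[1],
                          agent$press_force_range[2])
    ev <- c(ev, list(event_row(press_t, "lever_press", round(force, 2L)),
                     event_row(press_t, "spout_in"),
                     event_row(press_t + task$reward_window_s, "spout_out")))
    licks <- numeric(0)
    if (stats::runif(1) < sched$engage_prob) {
      lick_start <- press_t +
        rlnorm_mean(1, agent$press_to_lick_latency_s, agent$latency_cv)
      if (lick_start < span_end - 0.3)
        licks <- round(bout_licks(lick_start, agent$lick_rate_hz,
                                  agent$bout_duration_s, span_end - 0.1), 4L)
    }
    rewarded <- licks >= press_t & licks < press_t + task$reward_window_s
    for (k in seq_along(licks)) {
      ev <- c(ev, list(event_row(licks[k], "lick")))
      if (rewarded[k])
        ev <- c(ev, list(event_row(licks[k], "reward_delivery", 2)))
    }
    outcome <- if (any(rewarded)) "rewarded"
      else if (length(licks)) "non_rewarded" else "no_licks"
    trials[[i]] <- data.frame(trial_idx = i, latency_s = NA_real_,
                              outcome = outcome, stringsAsFactors = FALSE)
    trans <- c(trans, list(data.frame(
      time_s = press_t, linked_behavior = "lever_press", trial_idx = i,
      rewarded = any(rewarded), lick_end_s = NA_real_)))
    if (length(licks))
      trans <- c(trans, list(data.frame(
        time_s = licks[1], linked_behavior = "lick_bout_onset", trial_idx = i,
        rewarded = any(rewarded), lick_end_s = licks[length(licks)])))
    wait <- rlnorm_mean(1, sched$expected_latency_s, agent$latency_cv)
    t_now <- span_end + wait
  }
  # Phase II latency-to-press: wait from the previous trial's end (or from
  # session start for the first trial) to the opening press.
  if (length(trials)) {
    press_times <- vapply(trans[vapply(trans, function(d)
      d$linked_behavior == "lever_press", logical(1))],
      function(d) d$time_s, numeric(1))
    prev_end <- c(0, press_times[-length(press_times)] +
                    task$trial_duration_s)
    for (k in seq_along(trials)) trials[[k]]$latency_s <-
        press_times[k] - prev_end[k]
  }
  collect_session(ev, trials, trans)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

collect_session <- function(ev, trials, trans) {
  events <- do.call(rbind, ev)
  trials <- if (length(trials)) do.call(rbind, trials) else
    data.frame(trial_idx = integer(0), latency_s = numeric(0),
               outcome = character(0))
  transients <- if (length(trans)) do.call(rbind, trans) else
    data.frame(time_s = numeric(0), linked_behavior = character(0),
               trial_idx = integer(0), rewarded = logical(0),
               lick_end_s = numeric(0))
  transients <- transients[order(transients$time_s), , drop = FALSE]
  rownames(trials) <- rownames(transients) <- NULL
  list(events = events, trials = trials, transients = transients)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d trials, %d transients\n",
              nrow(x$trials), nrow(x$transients)))
  invisible(x)
}
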