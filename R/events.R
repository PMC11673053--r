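# Trial segmentation, outcome classification and behavioral metrics.
#
# Conventions used throughout: all windows are half-open [start, end) in
# seconds on the session master clock; a "rewarded lick" is a lick whose
# timestamp matches a reward_delivery within 1 ms (the rig logs the two
# jointly), which is robust to log truncation.

REWARD_MATCH_TOL_S <- 1e-3

#' Segment an event log into trials
#'
#' Phases I and III: one trial per `tone_on`, spanning from that tone to the
#' next one (or the session end), so licks in the intertrial interval belong
#' to the preceding trial; the cue window is the first `tone_duration_s` of
#' the trial. In Phase III the reward window opens at the first lever press
#' inside the cue and lasts `reward_window_s`. Phase II: one trial per
#' opening lever press (a press not inside a previous trial's
#' `trial_duration_s` span); a press during an open trial is logged as an
#' additional press of that trial, not a new one.
#'
#' Every event is assigned to exactly one trial or, if it falls before the
#' first trial or between Phase II trials, to the unassigned bucket
#' (`trial_idx = 0`).
#'
#' @param log An `event_log` with a known phase.
#' @param task A [task_config()] supplying window durations; defaults to the
#'   phase's standard protocol.
#' @return A `trial_set`: list with data frames `trials` (windows per trial)
#'   and `events` (the log's events tagged with `trial_idx`), plus the
#'   phase.
#' @export
segment_trials <- function(log, task = NULL) {
  stopifnot(inherits(log, "event_log"))
  phase <- log$meta$phase
  if (is.null(phase) || is.na(phase) || !phase %in% c("I", "II", "III"))
    stop("event log phase must be one of I, II, III", call. = FALSE)
  if (is.null(task)) task <- task_config(phase)
  ev <- log$events
  session_end <- if (nrow(ev)) max(ev$time_s) + 1e-6 else 0

  if (phase %in% c("I", "III")) {
    starts <- ev$time_s[ev$event == "tone_on"]
    ends <- c(starts[-1], session_end)
    cue_end <- starts + task$tone_duration_s
    n <- length(starts)
    rw_start <- rw_end <- rep(NA_real_, n)
    if (phase == "I") {
      rw_start <- starts
      rw_end <- cue_end
    } else if (n) {
      presses <- ev$time_s[ev$event == "lever_press"]
      for (i in seq_len(n)) {
        p <- presses[presses >= starts[i] & presses < cue_end[i]]
        if (length(p)) {
          rw_start[i] <- p[1]
          rw_end[i] <- p[1] + task$reward_window_s
        }
      }
    }
    trials <- data.frame(trial_idx = seq_len(n), phase = phase,
                         start_time_s = starts, end_time_s = ends,
                         cue_start_s = starts, cue_end_s = cue_end,
                         reward_start_s = rw_start, reward_end_s = rw_end,
                         stringsAsFactors = FALSE)
  } else {
    presses <- ev$time_s[ev$event == "lever_press"]
    starts <- numeric(0)
    open_until <- -Inf
    for (p in presses) {
      if (p >= open_until) {
        starts <- c(starts, p)
        open_until <- p + task$trial_duration_s
      }
    }
    n <- length(starts)
    trials <- data.frame(trial_idx = seq_len(n), phase = phase,
                         start_time_s = starts,
                         end_time_s = starts + task$trial_duration_s,
                         cue_start_s = NA_real_, cue_end_s = NA_real_,
                         reward_start_s = starts,
                         reward_end_s = starts + task$reward_window_s,
                         stringsAsFactors = FALSE)
  }

  idx <- rep(0L, nrow(ev))
  for (i in seq_len(nrow(trials)))
    idx[ev$time_s >= trials$start_time_s[i] &
          ev$time_s < trials$end_time_s[i]] <- trials$trial_idx[i]
  ev$trial_idx <- idx
  structure(list(trials = trials, events = ev, phase = phase,
                 meta = log$meta, task = task),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> phase %s: %d trials, %d events (%d unassigned)\n",
              x$phase, nrow(x$trials), nrow(x$events),
              sum(x$events$trial_idx == 0L)))
  invisible(x)
}

licks_rewarded <- function(lick_t, reward_t, tol = REWARD_MATCH_TOL_S) {
  if (!length(lick_t)) return(logical(0))
  if (!length(reward_t)) return(rep(FALSE, length(lick_t)))
  vapply(lick_t, function(t) any(abs(reward_t - t) <= tol), logical(1))
}

#' Classify the outcome of one trial
#'
#' A trial is `rewarded` iff it contains at least one lick coinciding with a
#' reward delivery. Otherwise: Phase III trials without any lever press are
#' `no_presses`; trials with licks but no rewarded lick are `non_rewarded`
#' (e.g., Phase I licking outside the tone window); trials without licks in
#' Phases I/II are `no_licks`.
#'
#' @param trial_events Data frame of the trial's events (columns `time_s`,
#'   `event`).
#' @param phase `"I"`, `"II"`, or `"III"`.
#' @return One of `"rewarded"`, `"non_rewarded"`, `"no_licks"`,
#'   `"no_presses"`.
#' @export
classify_trial <- function(trial_events, phase) {
  licks <- trial_events$time_s[trial_events$event == "lick"]
  rewards <- trial_events$time_s[trial_events$event == "reward_delivery"]
  presses <- trial_events$time_s[trial_events$event == "lever_press"]
  if (phase == "III" && !length(presses)) return("no_presses")
  if (any(licks_rewarded(licks, rewards))) return("rewarded")
  if (length(licks)) return("non_rewarded")
  if (phase == "III") return("non_rewarded")
  "no_licks"
}

#' Classify every trial in a trial set
#'
#' @param seg A `trial_set` from [segment_trials()].
#' @return The `trial_set` with an `outcome` column added to `$trials`.
#' @export
classify_trials <- function(seg) {
  stopifnot(inherits(seg, "trial_set"))
  seg$trials$outcome <- vapply(seg$trials$trial_idx, function(i)
    classify_trial(seg$events[seg$events$trial_idx == i, , drop = FALSE],
                   seg$phase), character(1))
  seg
}

#' Lick-bout onsets
#'
#' A bout onset is a lick preceded by at least `min_gap_s` without licking
#' (the first lick of the session always qualifies).
#'
#' @param lick_times Sorted lick timestamps (s).
#' @param min_gap_s Minimum lick-free gap defining a new bout.
#' @return Numeric vector of bout-onset times.
#' @export
lick_bout_onsets <- function(lick_times, min_gap_s = 1) {
  if (!length(lick_times)) return(numeric(0))
  lick_times <- sort(lick_times)
  lick_times[c(TRUE, diff(lick_times) >= min_gap_s)]
}

#' Per-trial behavioral metrics
#'
#' Computes, for each trial: the latency to the first lick from the trial
#' start, the latency to the first lever press (Phase III: from the tone
#' onset; Phase II: from the previous trial's end, since the press itself
#' starts the trial), the press-to-first-lick latency, lick and press
#' counts, and the trial outcome. Trials without the qualifying event carry
#' `NA` latencies, which are excluded from averages rather than zero-filled.
#'
#' @param seg A `trial_set`, classified or not (outcomes are computed if
#'   missing).
#' @return A data frame with one row per trial, carrying the session
#'   metadata columns `mouse`, `phase`, `day`, `test`.
#' @export
compute_metrics <- function(seg) {
  stopifnot(inherits(seg, "trial_set"))
  if (is.null(seg$trials$outcome)) seg <- classify_trials(seg)
  tr <- seg$trials
  n <- nrow(tr)
  if (!n) stop("no trials to compute metrics for", call. = FALSE)
  out <- tr[, c("trial_idx", "outcome")]
  out$mouse <- seg$meta$mouse
  out$phase <- seg$phase
  out$day <- seg$meta$day
  out$test <- seg$meta$test
  lat_lick <- lat_press <- lat_p2l <- rep(NA_real_, n)
  n_licks <- n_presses <- integer(n)
  prev_end <- 0
  for (i in seq_len(n)) {
    e <- seg$events[seg$events$trial_idx == tr$trial_idx[i], , drop = FALSE]
    licks <- e$time_s[e$event == "lick"]
    presses <- e$time_s[e$event == "lever_press"]
    n_licks[i] <- length(licks)
    n_presses[i] <- length(presses)
    if (length(licks)) lat_lick[i] <- min(licks) - tr$start_time_s[i]
    if (length(presses)) {
      ref <- if (seg$phase == "II") prev_end else tr$start_time_s[i]
      lat_press[i] <- min(presses) - ref
      after <- licks[licks >= min(presses)]
      if (length(after)) lat_p2l[i] <- min(after) - min(presses)
    }
    prev_end <- tr$end_time_s[i]
  }
  out$latency_first_lick_s <- lat_lick
  out$latency_first_press_s <- lat_press
  out$latency_press_to_first_lick_s <- lat_p2l
  out$n_licks <- n_licks
  out$n_presses <- n_presses
  out[, c("mouse", "phase", "day", "test", "trial_idx", "outcome",
          "latency_first_lick_s", "latency_first_press_s",
          "latency_press_to_first_lick_s", "n_licks", "n_presses")]
}

#' Per-test summary of behavioral metrics
#'
#' Averages the per-trial metrics within each (mouse, phase, day, test) and
#' adds the percentage of rewarded trials. `NA` latencies (trials without
#' the event) are excluded from the means.
#'
#' @param per_trial Output of [compute_metrics()] (rows from one or more
#'   sessions may be concatenated).
#' @return One row per (mouse, phase, day, test).
#' @export
summarize_tests <- function(per_trial) {
  key <- interaction(per_trial$mouse, per_trial$phase, per_trial$day,
                     per_trial$test, drop = TRUE)
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  rows <- lapply(split(per_trial, key), function(d) {
    data.frame(mouse = d$mouse[1], phase = d$phase[1], day = d$day[1],
               test = d$test[1],
               n_trials = nrow(d),
               latency_first_lick_s = mean_na(d$latency_first_lick_s),
               latency_first_press_s = mean_na(d$latency_first_press_s),
               latency_press_to_first_lick_s =
                 mean_na(d$latency_press_to_first_lick_s),
               n_licks = mean(d$n_licks),
               n_presses = mean(d$n_presses),
               pct_successful_trials = 100 * mean(d$outcome == "rewarded"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$mouse, res$phase, res$day, res$test), ]
  rownames(res) <- NULL
  res
}

#' Cohort summary by day and test
#'
#' Collapses per-test metrics across mice into a tidy long table of grand
#' mean +/- SEM per (phase, day, test, metric), with the SEM denominator
#' equal to the number of animals.
#'
#' @param test_tbl Output of [summarize_tests()] for one or more mice.
#' @return Long data frame with columns phase, day, test, metric, mean,
#'   sem, n.
#' @export
aggregate_by_day <- function(test_tbl) {
  key <- paste(test_tbl$mouse, test_tbl$phase, test_tbl$day, test_tbl$test)
  if (anyDuplicated(key))
    stop("duplicate (mouse, phase, day, test) keys", call. = FALSE)
  metrics <- c("latency_first_lick_s", "latency_first_press_s",
               "latency_press_to_first_lick_s", "n_licks", "n_presses",
               "pct_successful_trials")
  groups <- split(test_tbl,
                  interaction(test_tbl$phase, test_tbl$day, test_tbl$test,
                              drop = TRUE))
  rows <- lapply(groups, function(d) {
    do.call(rbind, lapply(metrics, function(m) {
      x <- d[[m]][!is.na(d[[m]])]
      n <- length(x)
      data.frame(phase = d$phase[1], day = d$day[1], test = d$test[1],
                 metric = m,
                 mean = if (n) mean(x) else NA_real_,
                 sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
                 n = n, stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$phase, res$day, res$test, res$metric), ]
  rownames(res) <- NULL
  res
}

#' Independent contingency replay check
#'
#' Re-scans a raw event log and verifies that every reward delivery
#' satisfies the phase's rule: Phase I -- the reward coincides with a lick
#' inside a tone window; Phase II -- the reward falls within
#' `reward_window_s` of a lever press; Phase III -- within `reward_window_s`
#' of a lever press that itself lies inside a tone window. The check works
#' directly from the event stream and is independent of trial segmentation
#' and of the simulator's bookkeeping.
#'
#' @param log An `event_log`.
#' @param task A [task_config()]; defaults to the phase's standard protocol.
#' @return A list with `n_rewards`, `n_violations`, and the violating
#'   timestamps `violations`.
#' @export
check_contingency <- function(log, task = NULL) {
  stopifnot(inherits(log, "event_log"))
  phase <- log$meta$phase
  if (is.null(task)) task <- task_config(phase)
  ev <- log$events
  rewards <- ev$time_s[ev$event == "reward_delivery"]
  licks <- ev$time_s[ev$event == "lick"]
  tone_on <- ev$time_s[ev$event == "tone_on"]
  tone_off <- ev$time_s[ev$event == "tone_off"]
  presses <- ev$time_s[ev$event == "lever_press"]
  in_tone <- function(t) {
    if (!length(tone_on)) return(rep(FALSE, length(t)))
    vapply(t, function(x) any(x >= tone_on &
                                x < tone_on + task$tone_duration_s),
           logical(1))
  }
  ok <- vapply(rewards, function(r) {
    has_lick <- any(abs(licks - r) <= REWARD_MATCH_TOL_S)
    rule <- switch(log$meta$phase,
      I = in_tone(r),
      II = length(presses) > 0 &&
        any(r >= presses & r < presses + task$reward_window_s),
      III = {
        valid <- presses[in_tone(presses)]
        length(valid) > 0 &&
          any(r >= valid & r < valid + task$reward_window_s)
      },
      FALSE)
    has_lick && isTRUE(rule)
  }, logical(1))
  list(n_rewards = length(rewards),
       n_violations = sum(!ok),
       violations = rewards[!ok])
}
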