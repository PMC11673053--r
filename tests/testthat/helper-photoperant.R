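# Shared fixtures: all synthetic, built in code at test time.

# A deterministic, fully engaged agent (no latency jitter): contingency
# outcomes are then forced by the task rules.
deterministic_agent <- function(latency = 1, seed = 1L) {
  agent_config(latency_init_s = latency, latency_asymptote_s = latency,
               engage_prob_init = 1, engage_prob_final = 1,
               latency_cv = 0, stray_lick_prob = 0, rng_seed = seed)
}

# An agent that never acts (anesthesia-like behavioral regime).
inactive_agent <- function(seed = 1L) {
  agent_config(engage_prob_init = 0, engage_prob_final = 0,
               stray_lick_prob = 0, rng_seed = seed)
}

# An already-proficient agent: latency and engagement at asymptote from
# day 1 (the cued-operant phase regime, where animals arrive trained).
proficient_agent <- function(seed = 1L) {
  agent_config(latency_init_s = 1, latency_asymptote_s = 1,
               engage_prob_init = 0.9, engage_prob_final = 0.9,
               rng_seed = seed)
}

# Build an event_log from an inline TSV body (header added automatically).
log_from_lines <- function(event_lines, phase = "I", day = 1, test = 1,
                           mouse = "t01") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(sprintf("# mouse=%s", mouse), sprintf("# phase=%s", phase),
               sprintf("# day=%d", day), sprintf("# test=%d", test),
               "time_s\tevent\tvalue", event_lines), path)
  read_event_log(path)
}

# Wrap a bare dff vector as a norm_trace for detector tests.
as_norm_trace <- function(dff, rate = 100, sd_method = "sd") {
  isosbestic_subtract(dff, rep(0, length(dff)),
                      time_s = (seq_along(dff) - 1) / rate,
                      sample_rate_hz = rate, sd_method = sd_method)
}

# Independent nested-loop rolling-mean delta-F/F oracle (shrinking window).
dff_oracle <- function(f, rate, window_s) {
  w <- max(1L, round(window_s * rate))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(f)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; cnt <- 0L
    for (j in max(1L, i - half):min(n, i + half)) {
      acc <- acc + f[j]; cnt <- cnt + 1L
    }
    b <- acc / cnt
    out[i] <- (f[i] - b) / b
  }
  out
}

# Independent excursion-scan peak oracle: one event per contiguous run of
# samples above threshold, at the run maximum, runs shorter than min_width
# samples discarded.
peak_oracle <- function(dff, time_s, thr, min_width_n = 1L) {
  peaks <- data.frame(time_s = numeric(0), amplitude = numeric(0))
  i <- 1L; n <- length(dff)
  while (i <= n) {
    if (dff[i] > thr) {
      j <- i
      while (j < n && dff[j + 1L] > thr) j <- j + 1L
      if (j - i + 1L >= min_width_n) {
        k <- i - 1L + which.max(dff[i:j])
        peaks <- rbind(peaks, data.frame(time_s = time_s[k],
                                         amplitude = dff[k]))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

# Match ground-truth transients to linked peaks; returns detected amplitude
# per transient (NA when missed or mislinked).
recovered_amplitudes <- function(truth, linked_peaks) {
  tt <- truth$transients
  vapply(seq_len(nrow(tt)), function(k) {
    i <- which(!is.na(linked_peaks$linked_time_s) &
                 abs(linked_peaks$linked_time_s - tt$time_s[k]) < 1e-6 &
                 linked_peaks$linked_kind == tt$linked_behavior[k])
    if (length(i)) linked_peaks$amplitude[i[1]] else NA_real_
  }, numeric(1))
}

# Simulate + process one session, returning everything downstream tests need.
processed_session <- function(phase, day, agent_seed, photo_seed = NULL,
                              agent = NULL, photo = NULL, task = NULL) {
  if (is.null(task)) task <- task_config(phase)
  if (is.null(agent)) agent <- agent_config(rng_seed = agent_seed)
  if (is.null(photo))
    photo <- photometry_config(rng_seed = photo_seed %||% (agent_seed + 7919))
  ses <- simulate_session(task, agent, photo, day = day)
  trace <- process_recording(ses$recording)
  seg <- classify_trials(segment_trials(ses$log, task))
  peaks <- link_peaks_to_behavior(detect_peaks(trace),
                                  behavior_anchor_events(seg))
  list(ses = ses, trace = trace, seg = seg, peaks = peaks, task = task)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
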