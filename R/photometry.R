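# Delta-F/F normalization, isosbestic artifact removal, peak detection and
# peri-event quantification.

# Centered moving average with the window shrinking at the edges; the width
# is forced odd so the window is symmetric around each sample.
centered_rolling_mean <- function(f, w) {
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(f)
  cs <- cumsum(c(0, f))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Rolling-mean delta-F/F normalization
#'
#' Normalizes a raw fluorescence channel as `(F(t) - B(t)) / B(t)`, where
#' the baseline `B(t)` is a centered rolling mean of the trace over
#' `window_s` seconds. At the edges the window shrinks to the available
#' samples. The ratio form makes the output invariant to rescaling the raw
#' trace by any positive constant, and slow baseline drift (photobleaching)
#' divides out because the window is long relative to calcium transients.
#'
#' @param f Numeric vector of raw fluorescence samples (must stay > 0 in
#'   rolling mean).
#' @param sample_rate_hz Sampling rate of `f`.
#' @param window_s Rolling-mean window length in seconds (default 30 s:
#'   long against ~1 s transients, short against bleaching).
#' @return Numeric vector of delta-F/F values, same length as `f`.
#' @export
normalize_dff <- function(f, sample_rate_hz, window_s = 30) {
  if (length(f) < 2)
    stop("trace too short to normalize (need >= 2 samples)", call. = FALSE)
  if (window_s <= 0) stop("window_s must be > 0", call. = FALSE)
  b <- centered_rolling_mean(f, max(1L, round(window_s * sample_rate_hz)))
  if (any(b <= 0))
    stop("rolling-mean baseline is non-positive; raw fluorescence must be positive",
         call. = FALSE)
  (f - b) / b
}

#' Isosbestic subtraction of normalized channels
#'
#' Subtracts the normalized 405 nm (calcium-independent) channel from the
#' normalized 465 nm channel to remove shared motion artifacts and
#' background fluctuations, and computes the session standard deviation of
#' the result (the reference for peak detection thresholds).
#'
#' @param dff465,dff405 Normalized channels on the same time grid.
#' @param time_s The shared time grid.
#' @param sample_rate_hz Sampling rate.
#' @param sd_method `"mad"` (default; the robust scale estimate
#'   `1.4826 * MAD`, insensitive to the transients being detected) or
#'   `"sd"` (plain standard deviation over the whole session).
#' @param provenance Optional list recorded in the output.
#' @return A `norm_trace`: list with `time_s`, `dff`, `session_sd`,
#'   `sample_rate_hz`, `provenance`.
#' @export
isosbestic_subtract <- function(dff465, dff405, time_s,
                                sample_rate_hz = NULL,
                                sd_method = c("mad", "sd"),
                                provenance = list()) {
  sd_method <- match.arg(sd_method)
  if (length(dff465) != length(dff405) || length(dff465) != length(time_s))
    stop("channel grids do not match", call. = FALSE)
  dff <- dff465 - dff405
  session_sd <- if (sd_method == "sd") stats::sd(dff)
    else stats::mad(dff)
  if (is.null(sample_rate_hz))
    sample_rate_hz <- 1 / stats::median(diff(time_s))
  structure(list(time_s = time_s, dff = dff, session_sd = session_sd,
                 sample_rate_hz = sample_rate_hz,
                 provenance = c(provenance, list(sd_method = sd_method))),
            class = "norm_trace")
}

#' @export
print.norm_trace <- function(x, ...) {
  cat(sprintf("<norm_trace> %d samples @ %g Hz, session SD %.4g\n",
              length(x$dff), x$sample_rate_hz, x$session_sd))
  invisible(x)
}

#' Full normalization of a two-channel recording
#'
#' Convenience wrapper: rolling-mean delta-F/F on each channel
#' ([normalize_dff()]) followed by unit-gain isosbestic subtraction
#' ([isosbestic_subtract()]). A least-squares-scaled subtraction (405
#' regressed onto 465) is available behind `fit_405 = TRUE` for rigs with
#' unequal channel artifact gains.
#'
#' @param rec A `photometry_recording`.
#' @param window_s Rolling-mean window (s).
#' @param sd_method Passed to [isosbestic_subtract()].
#' @param fit_405 If `TRUE`, scale the normalized 405 channel by its
#'   least-squares fit onto the 465 channel before subtracting.
#' @return A `norm_trace`.
#' @export
process_recording <- function(rec, window_s = 30, sd_method = "mad",
                              fit_405 = FALSE) {
  stopifnot(inherits(rec, "photometry_recording"))
  d465 <- normalize_dff(rec$F465, rec$sample_rate_hz, window_s)
  d405 <- normalize_dff(rec$F405, rec$sample_rate_hz, window_s)
  if (fit_405) {
    beta <- stats::coef(stats::lm.fit(cbind(1, d405), d465))[2]
    d405 <- beta * d405
  }
  isosbestic_subtract(d465, d405, rec$time_s, rec$sample_rate_hz,
                      sd_method = sd_method,
                      provenance = list(window_s = window_s,
                                        fit_405 = fit_405))
}

#' Detect calcium peak events
#'
#' Finds contiguous excursions of the trace above `threshold_sd` session
#' standard deviations and reports one event per excursion, at its maximum.
#' Two guards separate sensor noise from indicator transients: the trace is
#' lightly low-pass filtered (`smooth_s` boxcar) before thresholding so
#' that noise riding on a transient's decay cannot split one excursion into
#' several, and excursions shorter than `min_width_s` are rejected --
#' noise rarely stays above 2 SD for consecutive samples, whereas
#' transients (decay time constants of hundreds of milliseconds) do. The
#' threshold itself always references the session SD of the unsmoothed
#' trace.
#'
#' @param trace A `norm_trace`.
#' @param threshold_sd Threshold in session SD multiples (default 2).
#' @param min_width_s Minimum excursion duration (s); set to 0 to count
#'   every supra-threshold local maximum.
#' @param smooth_s Boxcar smoothing width (s) applied before thresholding;
#'   0 disables smoothing.
#' @return Data frame with columns `time_s`, `amplitude`, `threshold`.
#' @export
detect_peaks <- function(trace, threshold_sd = 2, min_width_s = 0.1,
                         smooth_s = 0.1) {
  stopifnot(inherits(trace, "norm_trace"))
  thr <- threshold_sd * trace$session_sd
  empty <- data.frame(time_s = numeric(0), amplitude = numeric(0),
                      threshold = numeric(0))
  if (!is.finite(thr) || trace$session_sd == 0) return(empty)
  dff <- trace$dff
  sw <- round(smooth_s * trace$sample_rate_hz)
  if (sw > 1L) dff <- centered_rolling_mean(dff, sw)
  above <- dff > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= max(1L, round(min_width_s *
                                                  trace$sample_rate_hz))
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  peak_at <- mapply(function(s, e) s - 1L + which.max(dff[s:e]),
                    starts, ends)
  data.frame(time_s = trace$time_s[peak_at],
             amplitude = dff[peak_at],
             threshold = thr)
}

#' Behavioral events that anchor calcium transients
#'
#' Extracts, per trial, the opening lever press and every lick-bout onset
#' (first lick after >= `bout_gap_s` without licking), the two behavioral
#' instants to which calcium peaks are attributed.
#'
#' @param seg A `trial_set`.
#' @param bout_gap_s Minimum lick-free gap defining a bout onset.
#' @return Data frame with columns `time_s`, `kind`
#'   (`lever_press`/`lick_bout_onset`), `trial_idx`.
#' @export
behavior_anchor_events <- function(seg, bout_gap_s = 1) {
  stopifnot(inherits(seg, "trial_set"))
  ev <- seg$events
  rows <- list()
  for (i in seg$trials$trial_idx) {
    e <- ev[ev$trial_idx == i, , drop = FALSE]
    presses <- e$time_s[e$event == "lever_press"]
    if (length(presses))
      rows <- c(rows, list(data.frame(time_s = presses[1],
                                      kind = "lever_press", trial_idx = i)))
    onsets <- lick_bout_onsets(e$time_s[e$event == "lick"], bout_gap_s)
    if (length(onsets))
      rows <- c(rows, list(data.frame(time_s = onsets,
                                      kind = "lick_bout_onset",
                                      trial_idx = i)))
  }
  if (!length(rows))
    return(data.frame(time_s = numeric(0), kind = character(0),
                      trial_idx = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$time_s), ]
  rownames(out) <- NULL
  out
}

#' Link detected peaks to behavioral events
#'
#' Each behavioral event claims at most one peak: events are visited in
#' chronological order (so the earlier event wins ties) and each claims the
#' nearest unclaimed peak within `[event, event + association_window_s)`.
#' Unlinked peaks are retained with `NA` link fields.
#'
#' @param peaks Data frame from [detect_peaks()].
#' @param behavior Data frame from [behavior_anchor_events()] (columns
#'   `time_s`, `kind`, optionally `trial_idx`).
#' @param association_window_s Window after the behavioral event within
#'   which a peak may be attributed to it (default 2 s).
#' @return `peaks` with added columns `linked_kind`, `linked_time_s`,
#'   `lag_s`, `linked_trial_idx`.
#' @export
link_peaks_to_behavior <- function(peaks, behavior,
                                   association_window_s = 2) {
  peaks$linked_kind <- NA_character_
  peaks$linked_time_s <- NA_real_
  peaks$lag_s <- NA_real_
  peaks$linked_trial_idx <- NA_integer_
  if (!nrow(peaks) || !nrow(behavior)) return(peaks)
  behavior <- behavior[order(behavior$time_s), , drop = FALSE]
  claimed <- rep(FALSE, nrow(peaks))
  for (j in seq_len(nrow(behavior))) {
    lag <- peaks$time_s - behavior$time_s[j]
    cand <- which(!claimed & lag >= 0 & lag < association_window_s)
    if (!length(cand)) next
    pick <- cand[which.min(lag[cand])]
    claimed[pick] <- TRUE
    peaks$linked_kind[pick] <- behavior$kind[j]
    peaks$linked_time_s[pick] <- behavior$time_s[j]
    peaks$lag_s[pick] <- lag[pick]
    peaks$linked_trial_idx[pick] <-
      if (!is.null(behavior$trial_idx)) behavior$trial_idx[j] else NA_integer_
  }
  peaks
}

#' Build a peri-event matrix
#'
#' One row per trial containing the alignment event, sampled on a common
#' time grid `[-pre_s, post_s)` around the event by nearest-sample lookup
#' (no interpolation; the grid inherits the recording's sample rate). Rows
#' whose window extends beyond the recording are flagged incomplete and
#' padded with `NA`, never silently extrapolated.
#'
#' @param trace A `norm_trace`.
#' @param seg A classified `trial_set` (outcomes label the rows).
#' @param align_on `"tone_on"` (trial/cue start), `"lever_press"` (first
#'   press of the trial) or `"lick_bout_onset"` (first bout onset).
#' @param pre_s,post_s Window extent before/after the event (s).
#' @return A `peri_event_matrix`: list with `mat` (trials x bins), `time_s`
#'   (bin offsets), `outcome`, `trial_idx`, `incomplete`, `align_on`.
#' @export
build_peri_event_matrix <- function(trace, seg,
                                    align_on = c("tone_on", "lever_press",
                                                 "lick_bout_onset"),
                                    pre_s = 2, post_s = 8) {
  stopifnot(inherits(trace, "norm_trace"), inherits(seg, "trial_set"))
  align_on <- match.arg(align_on)
  if (is.null(seg$trials$outcome)) seg <- classify_trials(seg)
  dt <- 1 / trace$sample_rate_hz
  offsets <- seq(-pre_s, post_s - dt / 2, by = dt)
  t0 <- trace$time_s[1]
  n <- length(trace$dff)

  align_time <- function(i) {
    e <- seg$events[seg$events$trial_idx == i, , drop = FALSE]
    switch(align_on,
           tone_on = {
             ct <- seg$trials$cue_start_s[seg$trials$trial_idx == i]
             if (is.na(ct)) seg$trials$start_time_s[seg$trials$trial_idx == i]
             else ct
           },
           lever_press = {
             p <- e$time_s[e$event == "lever_press"]
             if (length(p)) p[1] else NA_real_
           },
           lick_bout_onset = {
             o <- lick_bout_onsets(e$time_s[e$event == "lick"])
             if (length(o)) o[1] else NA_real_
           })
  }
  at <- vapply(seg$trials$trial_idx, align_time, numeric(1))
  keep <- which(!is.na(at))
  mat <- matrix(NA_real_, length(keep), length(offsets))
  incomplete <- logical(length(keep))
  for (r in seq_along(keep)) {
    idx <- round((at[keep[r]] + offsets - t0) / dt) + 1L
    ok <- idx >= 1L & idx <= n
    incomplete[r] <- any(!ok)
    mat[r, ok] <- trace$dff[idx[ok]]
  }
  structure(list(mat = mat, time_s = offsets,
                 outcome = seg$trials$outcome[keep],
                 trial_idx = seg$trials$trial_idx[keep],
                 incomplete = incomplete, align_on = align_on),
            class = "peri_event_matrix")
}

#' @export
print.peri_event_matrix <- function(x, ...) {
  cat(sprintf("<peri_event_matrix> %d trials x %d bins, aligned on %s\n",
              nrow(x$mat), ncol(x$mat), x$align_on))
  invisible(x)
}

#' Group-mean peri-event traces by trial outcome
#'
#' @param pem A `peri_event_matrix`.
#' @return Long data frame with columns `outcome`, `time_s`, `mean`, `sem`,
#'   `n` (trial-level n within the session).
#' @export
peri_event_group_means <- function(pem) {
  stopifnot(inherits(pem, "peri_event_matrix"))
  rows <- lapply(split(seq_len(nrow(pem$mat)), pem$outcome), function(idx) {
    m <- pem$mat[idx, , drop = FALSE]
    n_col <- colSums(!is.na(m))
    mu <- colMeans(m, na.rm = TRUE)
    sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
    data.frame(outcome = pem$outcome[idx[1]], time_s = pem$time_s,
               mean = mu, sem = ifelse(n_col > 1, sdv / sqrt(n_col), NA),
               n = n_col, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Windowed per-trial peak amplitude
#'
#' For each row of a peri-event matrix, the maximum of the trace within
#' `[window[1], window[2])` relative to the alignment event -- e.g. the max
#' peak within the first 2 s of the tone when the matrix is tone-aligned.
#'
#' @param pem A `peri_event_matrix`.
#' @param window Numeric `c(t0, t1)`, seconds relative to alignment; must
#'   lie inside the matrix span.
#' @return Data frame with `trial_idx`, `outcome`, `amplitude`.
#' @export
window_peak_amplitude <- function(pem, window = c(0, 2)) {
  stopifnot(inherits(pem, "peri_event_matrix"))
  dt <- pem$time_s[2] - pem$time_s[1]
  if (window[1] < pem$time_s[1] - 1e-9 ||
      window[2] > pem$time_s[length(pem$time_s)] + dt + 1e-9)
    stop("window outside the peri-event matrix span", call. = FALSE)
  cols <- pem$time_s >= window[1] & pem$time_s < window[2]
  if (!any(cols)) stop("window contains no bins", call. = FALSE)
  amp <- apply(pem$mat[, cols, drop = FALSE], 1L, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  data.frame(trial_idx = pem$trial_idx, outcome = pem$outcome,
             amplitude = amp)
}

#' Linked-peak amplitude by training day
#'
#' Mean +/- SEM of the amplitudes of behavior-linked peaks per (day,
#' behavior kind). Expects the linked-peak table to carry a `day` column
#' (added by the pipeline when concatenating sessions).
#'
#' @param linked_peaks Data frame from [link_peaks_to_behavior()] with an
#'   added `day` column; unlinked peaks are ignored.
#' @return Tidy data frame with `day`, `kind`, `mean_amplitude`, `sem`,
#'   `n_peaks`.
#' @export
peak_amplitude_by_day <- function(linked_peaks) {
  lp <- linked_peaks[!is.na(linked_peaks$linked_kind), , drop = FALSE]
  if (!nrow(lp))
    return(data.frame(day = integer(0), kind = character(0),
                      mean_amplitude = numeric(0), sem = numeric(0),
                      n_peaks = integer(0)))
  groups <- split(lp, interaction(lp$day, lp$linked_kind, drop = TRUE))
  out <- do.call(rbind, lapply(groups, function(d) {
    data.frame(day = d$day[1], kind = d$linked_kind[1],
               mean_amplitude = mean(d$amplitude),
               sem = if (nrow(d) > 1)
                 stats::sd(d$amplitude) / sqrt(nrow(d)) else NA_real_,
               n_peaks = nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$kind, out$day), ]
  rownames(out) <- NULL
  out
}
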