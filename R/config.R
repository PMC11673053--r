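#' Box geometry for the operant chamber
#'
#' Coordinates are in millimetres in an image-style frame (origin at the
#' top-left corner, y increasing downwards), matching the convention of pose
#' files exported from video tracked from below the box.
#'
#' @param width_mm,height_mm Interior box dimensions.
#' @param spout_xy,lever_xy Coordinates of the reward spout and the lever.
#' @return A list with class `"box_geometry"`.
#' @export
box_geometry <- function(width_mm = 200, height_mm = 150,
                         spout_xy = c(100, 10), lever_xy = c(160, 10)) {
  stopifnot(width_mm > 0, height_mm > 0,
            length(spout_xy) == 2, length(lever_xy) == 2)
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 spout_xy = as.numeric(spout_xy),
                 lever_xy = as.numeric(lever_xy)),
            class = "box_geometry")
}

#' Task configuration for one conditioning phase
#'
#' Defaults encode the study protocol: a 5 s tone followed by a 15 s
#' intertrial interval in the cued phases, 10 s press-initiated trials and
#' 5 min free-operant tests in Phase II, two tests per day, 5--10 trials per
#' test, and 8/6/5 training days for Phases I/II/III.
#'
#' @param phase `"I"` (classical conditioning: licks during the tone are
#'   rewarded), `"II"` (operant: a lever press opens the spout), or `"III"`
#'   (cued operant: only a press during the tone opens the spout).
#' @param tone_duration_s Conditioned-stimulus duration (s).
#' @param intertrial_interval_s Interval after the tone in Phases I/III (s).
#' @param reward_window_s How long the spout stays available after a valid
#'   trigger in Phases II/III (s).
#' @param trial_duration_s Span of one press-initiated Phase II trial (s).
#' @param trials_per_test Integer range `c(min, max)`; the number of trials
#'   in a cued test is drawn uniformly from this range.
#' @param tests_per_day Tests per training day.
#' @param days Training days for this phase; default 8, 6, or 5 for Phases
#'   I, II, III respectively.
#' @param test_duration_s Duration of a Phase II free-operant test (s).
#' @param geometry A [box_geometry()] used by the pose simulator.
#' @return A list with class `"task_config"`.
#' @export
task_config <- function(phase = c("I", "II", "III"),
                        tone_duration_s = 5,
                        intertrial_interval_s = 15,
                        reward_window_s = 5,
                        trial_duration_s = 10,
                        trials_per_test = c(5L, 10L),
                        tests_per_day = 2L,
                        days = NULL,
                        test_duration_s = 300,
                        geometry = box_geometry()) {
  phase <- match.arg(phase)
  if (is.null(days)) days <- c(I = 8L, II = 6L, III = 5L)[[phase]]
  durs <- c(tone_duration_s, intertrial_interval_s, reward_window_s,
            trial_duration_s, test_duration_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("all task durations must be finite and > 0", call. = FALSE)
  trials_per_test <- as.integer(trials_per_test)
  if (length(trials_per_test) == 1L)
    trials_per_test <- rep(trials_per_test, 2L)
  if (trials_per_test[1] < 1L || trials_per_test[2] < trials_per_test[1])
    stop("trials_per_test must be an increasing range with lower bound >= 1",
         call. = FALSE)
  if (days < 1L) stop("days must be >= 1", call. = FALSE)
  if (!inherits(geometry, "box_geometry"))
    stop("geometry must be a box_geometry()", call. = FALSE)
  structure(list(phase = phase,
                 tone_duration_s = tone_duration_s,
                 intertrial_interval_s = intertrial_interval_s,
                 reward_window_s = reward_window_s,
                 trial_duration_s = trial_duration_s,
                 trials_per_test = trials_per_test,
                 tests_per_day = as.integer(tests_per_day),
                 days = as.integer(days),
                 test_duration_s = test_duration_s,
                 geometry = geometry),
            class = "task_config")
}

#' Virtual-mouse (agent) configuration
#'
#' The agent's expected action latency relaxes exponentially from
#' `latency_init_s` to `latency_asymptote_s` with time constant
#' `learning_tau_days`, and its probability of attempting the correct action
#' rises from `engage_prob_init` to `engage_prob_final` on the same
#' exponential schedule (see [learning_schedule()]). Individual latencies
#' are drawn log-normally around the schedule with coefficient of variation
#' `latency_cv`. Licking is modeled as a regular train at `lick_rate_hz`
#' lasting `bout_duration_s`.
#'
#' @param latency_init_s,latency_asymptote_s Expected action latency on day 1
#'   and at asymptote (s); the asymptote must not exceed the initial value.
#' @param learning_tau_days Learning time constant (days).
#' @param engage_prob_init,engage_prob_final Probability of attempting the
#'   phase's correct action on a given trial, day 1 vs. asymptote.
#' @param lick_rate_hz Within-bout lick rate (Hz).
#' @param bout_duration_s Lick-bout duration (s).
#' @param press_force_range Range of lever-press forces (arbitrary units).
#' @param latency_cv Coefficient of variation of log-normal latency draws.
#' @param press_to_lick_latency_s Expected delay from lever press to the
#'   first lick of the consumption bout (Phases II/III, s).
#' @param stray_lick_prob Probability that a disengaged cued trial still
#'   contains an off-cue lick bout (produces non-rewarded trials).
#' @param rng_seed Base seed; each session derives its own stream from it.
#' @return A list with class `"agent_config"`.
#' @export
agent_config <- function(latency_init_s = 6, latency_asymptote_s = 1,
                         learning_tau_days = 1.5,
                         engage_prob_init = 0.3, engage_prob_final = 0.9,
                         lick_rate_hz = 8, bout_duration_s = 2,
                         press_force_range = c(10, 50),
                         latency_cv = 0.3,
                         press_to_lick_latency_s = 3,
                         stray_lick_prob = 0.5,
                         rng_seed = 1L) {
  probs <- c(engage_prob_init, engage_prob_final, stray_lick_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (latency_asymptote_s > latency_init_s)
    stop("latency_asymptote_s must not exceed latency_init_s", call. = FALSE)
  if (lick_rate_hz <= 0) stop("lick_rate_hz must be > 0", call. = FALSE)
  if (learning_tau_days <= 0)
    stop("learning_tau_days must be > 0", call. = FALSE)
  if (latency_cv < 0) stop("latency_cv must be >= 0", call. = FALSE)
  structure(list(latency_init_s = latency_init_s,
                 latency_asymptote_s = latency_asymptote_s,
                 learning_tau_days = learning_tau_days,
                 engage_prob_init = engage_prob_init,
                 engage_prob_final = engage_prob_final,
                 lick_rate_hz = lick_rate_hz,
                 bout_duration_s = bout_duration_s,
                 press_force_range = as.numeric(press_force_range),
                 latency_cv = latency_cv,
                 press_to_lick_latency_s = press_to_lick_latency_s,
                 stray_lick_prob = stray_lick_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "agent_config")
}

#' Generative photometry configuration
#'
#' Parameters of the two-channel fluorescence model used by
#' [generate_photometry()]. Transient amplitudes are specified directly in
#' delta-F/F units (the kernel is normalized to unit peak), so ground-truth
#' amplitudes are directly comparable with pipeline output. Kinetics default
#' to fast-GCaMP-like values (rise 0.1 s, decay 0.8 s).
#'
#' @param sample_rate_hz Sampling rate of both channels (Hz).
#' @param transient_amp_rewarded,transient_amp_nonrewarded Peak transient
#'   amplitude (delta-F/F) on rewarded vs. non-rewarded trials.
#' @param tau_rise_s,tau_decay_s Transient kernel time constants (s);
#'   `tau_rise_s < tau_decay_s`.
#' @param consumption_dip_amp Magnitude of the negative deflection during
#'   reward consumption (delta-F/F; applied as a negative dip).
#' @param bleach_tau_s Photobleaching time constant (s).
#' @param artifact_rate_hz,artifact_amp Rate and typical magnitude of shared
#'   motion artifacts (delta-F/F equivalents injected into both channels).
#' @param artifact_gain_405 Relative artifact gain on the 405 channel; with
#'   gain 1 isosbestic subtraction cancels the artifact exactly.
#' @param noise_sd Additive sensor noise, as a fraction of each channel's
#'   baseline fluorescence.
#' @param baseline_F465,baseline_F405 Raw baseline fluorescence per channel
#'   (arbitrary units).
#' @param rng_seed Base seed for the photometry noise stream.
#' @return A list with class `"photometry_config"`.
#' @export
photometry_config <- function(sample_rate_hz = 100,
                              transient_amp_rewarded = 0.06,
                              transient_amp_nonrewarded = 0.02,
                              tau_rise_s = 0.1, tau_decay_s = 0.8,
                              consumption_dip_amp = 0.02,
                              bleach_tau_s = 3000,
                              artifact_rate_hz = 0.05, artifact_amp = 0.02,
                              artifact_gain_405 = 1,
                              noise_sd = 0.002,
                              baseline_F465 = 100, baseline_F405 = 80,
                              rng_seed = 1L) {
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be > 0", call. = FALSE)
  if (tau_rise_s >= tau_decay_s)
    stop("tau_rise_s must be smaller than tau_decay_s", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (baseline_F465 <= 0 || baseline_F405 <= 0)
    stop("baseline fluorescence must be > 0", call. = FALSE)
  structure(list(sample_rate_hz = sample_rate_hz,
                 transient_amp_rewarded = transient_amp_rewarded,
                 transient_amp_nonrewarded = transient_amp_nonrewarded,
                 tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
                 consumption_dip_amp = consumption_dip_amp,
                 bleach_tau_s = bleach_tau_s,
                 artifact_rate_hz = artifact_rate_hz,
                 artifact_amp = artifact_amp,
                 artifact_gain_405 = artifact_gain_405,
                 noise_sd = noise_sd,
                 baseline_F465 = baseline_F465,
                 baseline_F405 = baseline_F405,
                 rng_seed = as.integer(rng_seed)),
            class = "photometry_config")
}

# Deterministic per-session seed stream: keeps all draws for one session on
# one seed while separating (phase, day, test, purpose). Stays below 2^31.
session_seed <- function(base, phase, day, test, offset = 0L) {
  p <- match(phase, c("I", "II", "III"))
  if (is.na(p)) p <- 0L
  as.integer((abs(as.numeric(base)) * 40503 + p * 1299721 +
                as.numeric(day) * 7919 + as.numeric(test) * 104729 +
                as.numeric(offset)) %% 2147483629)
}

# Log-normal draws with a given mean and coefficient of variation.
rlnorm_mean <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
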