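# Double-exponential transient kernel, normalized to unit peak so that the
# configured amplitude is directly a delta-F/F peak height.
transient_kernel <- function(t, tau_rise, tau_decay) {
  g <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  g[t < 0] <- 0
  t_pk <- tau_rise * log(1 + tau_decay / tau_rise)
  g / ((1 - exp(-t_pk / tau_rise)) * exp(-t_pk / tau_decay))
}

# Time of the kernel maximum (closed form).
transient_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * log(1 + tau_decay / tau_rise)
}

#' Generate a two-channel photometry recording for a simulated session
#'
#' Builds raw 405/465 nm fluorescence traces on a uniform grid spanning the
#' event log. The 465 channel is `baseline * bleach(t) * (1 + s(t) + a(t)) +
#' noise`, where `s(t)` sums unit-peak transient kernels placed at the
#' ground-truth transient times (amplitude chosen by trial outcome) minus a
#' smooth consumption dip during rewarded lick bouts, and `a(t)` is a shared
#' motion-artifact series. The 405 isosbestic channel carries the same
#' multiplicative bleaching and artifact (scaled by `artifact_gain_405`) but
#' no calcium transients, so unit-gain isosbestic subtraction of the
#' normalized channels cancels the artifact exactly in the noise-free case.
#'
#' @param log An `event_log` from [run_task_state_machine()].
#' @param truth The matching `sim_truth`; returned updated with the injected
#'   amplitude per transient and the realized artifact series.
#' @param cfg A [photometry_config()].
#' @param seed Seed for the noise/artifact stream; defaults to a stream
#'   derived from `cfg$rng_seed` and the session coordinates.
#' @return A list with elements `recording` (a `photometry_recording`) and
#'   `truth` (the augmented `sim_truth`).
#' @export
generate_photometry <- function(log, truth, cfg = photometry_config(),
                                seed = NULL) {
  stopifnot(inherits(log, "event_log"), inherits(truth, "sim_truth"),
            inherits(cfg, "photometry_config"))
  if (!nrow(log$events)) stop("event log is empty", call. = FALSE)
  if (is.null(seed))
    seed <- session_seed(cfg$rng_seed, log$meta$phase, log$meta$day,
                         log$meta$test, offset = 500009L)
  set.seed(seed)

  warnings <- character(0)
  if (cfg$sample_rate_hz * cfg$tau_rise_s < 2)
    warnings <- c(warnings,
                  "sample rate below 2 samples per tau_rise; transients undersampled")

  t_end <- max(log$events$time_s) + 10
  dt <- 1 / cfg$sample_rate_hz
  time <- seq(0, t_end, by = dt)
  n <- length(time)
  bleach <- exp(-time / cfg$bleach_tau_s)

  # transients and consumption dips
  s <- numeric(n)
  tr <- truth$transients
  amp <- numeric(nrow(tr))
  if (nrow(tr)) {
    amp <- ifelse(tr$rewarded, cfg$transient_amp_rewarded,
                  cfg$transient_amp_nonrewarded)
    support <- transient_peak_time(cfg$tau_rise_s, cfg$tau_decay_s) +
      9 * cfg$tau_decay_s
    for (k in seq_len(nrow(tr))) {
      i0 <- max(1L, floor(tr$time_s[k] / dt) + 1L)
      i1 <- min(n, ceiling((tr$time_s[k] + support) / dt) + 1L)
      idx <- i0:i1
      s[idx] <- s[idx] + amp[k] *
        transient_kernel(time[idx] - tr$time_s[k],
                         cfg$tau_rise_s, cfg$tau_decay_s)
    }
    # consumption dip during rewarded lick bouts: delayed smooth trapezoid
    dips <- tr[tr$linked_behavior == "lick_bout_onset" & tr$rewarded &
                 !is.na(tr$lick_end_s), , drop = FALSE]
    for (k in seq_len(nrow(dips))) {
      on <- dips$time_s[k] + 0.5
      off <- dips$lick_end_s[k] + 0.3
      shape <- pmin(1, pmax(0, (time - on) / 0.3)) *
        ifelse(time <= off, 1, exp(-(time - off) / 0.5))
      shape[time < on] <- 0
      s <- s - cfg$consumption_dip_amp * shape
    }
  }
  truth$transients$amplitude <- amp

  # shared motion artifacts: sharp biexponential deflections, random sign
  a <- numeric(n)
  n_art <- stats::rpois(1, cfg$artifact_rate_hz * t_end)
  if (n_art > 0) {
    art_t <- sort(stats::runif(n_art, 0, t_end))
    art_a <- cfg$artifact_amp * stats::runif(n_art, 0.7, 1.3) *
      sample(c(-1, 1), n_art, replace = TRUE)
    for (k in seq_len(n_art)) {
      i0 <- max(1L, floor((art_t[k] - 0.5) / dt) + 1L)
      i1 <- min(n, ceiling((art_t[k] + 0.5) / dt) + 1L)
      idx <- i0:i1
      a[idx] <- a[idx] + art_a[k] * exp(-abs(time[idx] - art_t[k]) / 0.05)
    }
  }
  truth$artifact_dff <- a

  F465 <- cfg$baseline_F465 * bleach * (1 + s + a) +
    stats::rnorm(n, 0, cfg$noise_sd * cfg$baseline_F465)
  F405 <- cfg$baseline_F405 * bleach * (1 + cfg$artifact_gain_405 * a) +
    stats::rnorm(n, 0, cfg$noise_sd * cfg$baseline_F405)

  rec <- structure(list(time_s = time, F405 = F405, F465 = F465,
                        sample_rate_hz = cfg$sample_rate_hz,
                        sync_offset_s = 0,
                        meta = log$meta,
                        provenance = list(seed = seed, warnings = warnings)),
                   class = "photometry_recording")
  list(recording = rec, truth = truth)
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$time_s), x$sample_rate_hz, max(x$time_s)))
  invisible(x)
}

#' Generate a synthetic body-part tracking table for a session
#'
#' A smoothed random walk over the box that is attracted to the lever
#' shortly before each lever press and to the spout around each lick bout,
#' and wanders around the box center otherwise. Seven body parts (head, four
#' paws, rear of body, tail) are derived from the body position with fixed
#' offsets plus jitter; per-frame confidences are high with occasional
#' dropouts.
#'
#' @param log An `event_log`.
#' @param task The [task_config()] supplying the box geometry.
#' @param agent An [agent_config()] (bout duration shapes spout visits).
#' @param frame_rate_hz Video frame rate.
#' @param seed Seed for the walk; defaults to a session-derived stream.
#' @return A `pose_track`: list with `frame_rate_hz`, `parts`, and a long
#'   data frame `data` with columns frame, time_s, part, x, y, likelihood.
#' @export
generate_pose_track <- function(log, task, agent, frame_rate_hz = 30,
                                seed = NULL) {
  stopifnot(inherits(log, "event_log"), inherits(task, "task_config"))
  if (is.null(seed))
    seed <- session_seed(agent$rng_seed, log$meta$phase, log$meta$day,
                         log$meta$test, offset = 900007L)
  set.seed(seed)
  geom <- task$geometry
  dur <- max(log$events$time_s) + 5
  n <- floor(dur * frame_rate_hz)
  t <- (seq_len(n) - 1) / frame_rate_hz

  # target timeline: spout around licks, lever before presses, else center
  target <- matrix(rep(c(geom$width_mm / 2, geom$height_mm / 2), each = n),
                   ncol = 2)
  set_target <- function(target, t0, t1, xy) {
    idx <- which(t >= t0 & t <= t1)
    target[idx, 1] <- xy[1]; target[idx, 2] <- xy[2]
    target
  }
  ev <- log$events
  for (tp in ev$time_s[ev$event == "lever_press"])
    target <- set_target(target, tp - 1.5, tp + 0.5, geom$lever_xy)
  for (tl in ev$time_s[ev$event == "lick"])
    target <- set_target(target, tl - 1, tl + 0.2, geom$spout_xy)

  pos <- matrix(0, n, 2)
  pos[1, ] <- c(geom$width_mm / 2, geom$height_mm / 2)
  k <- 3 / frame_rate_hz           # attraction per frame
  sd_step <- 25 / frame_rate_hz    # wander scale (mm per frame)
  for (i in 2:n) {
    pos[i, ] <- pos[i - 1, ] + k * (target[i, ] - pos[i - 1, ]) +
      stats::rnorm(2, 0, sd_step)
    pos[i, 1] <- min(max(pos[i, 1], 2), geom$width_mm - 2)
    pos[i, 2] <- min(max(pos[i, 2], 2), geom$height_mm - 2)
  }

  parts <- c("head", "paw_front_left", "paw_front_right", "paw_hind_left",
             "paw_hind_right", "body_rear", "tail")
  offs <- rbind(c(0, -8), c(-6, -4), c(6, -4), c(-7, 8), c(7, 8),
                c(0, 14), c(0, 26))
  rows <- vector("list", length(parts))
  for (p in seq_along(parts)) {
    x <- pos[, 1] + offs[p, 1] + stats::rnorm(n, 0, 1)
    y <- pos[, 2] + offs[p, 2] + stats::rnorm(n, 0, 1)
    lik <- pmin(1, pmax(0, stats::rbeta(n, 20, 1)))
    drop <- stats::runif(n) < 0.02
    lik[drop] <- stats::runif(sum(drop), 0, 0.3)
    rows[[p]] <- data.frame(frame = seq_len(n) - 1L, time_s = t,
                            part = parts[p],
                            x = pmin(pmax(x, 0), geom$width_mm),
                            y = pmin(pmax(y, 0), geom$height_mm),
                            likelihood = round(lik, 4),
                            stringsAsFactors = FALSE)
  }
  structure(list(frame_rate_hz = frame_rate_hz, parts = parts,
                 meta = log$meta,
                 data = do.call(rbind, rows)),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames @ %g Hz, %d parts\n",
              length(unique(x$data$frame)), x$frame_rate_hz, length(x$parts)))
  invisible(x)
}
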