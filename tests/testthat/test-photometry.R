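test_that("rolling-mean dF/F equals the nested-loop oracle", {
  set.seed(42)
  for (k in 1:50) {
    n <- sample(5:60, 1)
    f <- runif(n, 50, 150)
    rate <- sample(c(1, 10, 100), 1)
    window_s <- runif(1, 1 / rate, n / rate)
    got <- normalize_dff(f, rate, window_s)
    want <- dff_oracle(f, rate, window_s)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-12)), 1e-10)
  }
})

test_that("dF/F of a constant trace is zero and scaling leaves it unchanged", {
  expect_equal(normalize_dff(rep(7, 100), 10, 2), rep(0, 100))
  set.seed(1)
  f <- 100 + cumsum(rnorm(200, 0, 0.1))
  base <- normalize_dff(f, 20, 3)
  for (c in c(0.5, 3, 1000))
    expect_equal(normalize_dff(c * f, 20, 3), base, tolerance = 1e-12)
})

test_that("dF/F rejects degenerate input", {
  expect_error(normalize_dff(c(1), 10), "too short")
  expect_error(normalize_dff(c(1, -5, 1, 1, 1, -5), 1, 6), "positive")
  expect_error(normalize_dff(1:10, 10, 0), "window_s")
})

test_that("isosbestic subtraction removes the common component", {
  t <- seq(0, 10, by = 0.01)
  a <- 0.02 * sin(t); b <- 0.001 * cos(3 * t); common <- 0.05 * sin(7 * t)
  plain <- isosbestic_subtract(a, b, t)
  shifted <- isosbestic_subtract(a + common, b + common, t)
  expect_equal(shifted$dff, plain$dff, tolerance = 1e-12)
  # a zero reference channel passes the 465 trace through
  expect_equal(isosbestic_subtract(a, rep(0, length(a)), t)$dff, a)
  expect_error(isosbestic_subtract(a, b[-1], t), "grids")
})

test_that("matched-gain subtraction cancels an injected artifact", {
  task <- task_config("I")
  s <- run_task_state_machine(task, inactive_agent(7L), day = 1)
  out <- generate_photometry(s$log, s$truth,
                             photometry_config(noise_sd = 0,
                                               artifact_rate_hz = 0.3,
                                               rng_seed = 3L))
  rec <- out$recording
  art <- out$truth$artifact_dff
  expect_gt(sum(art^2), 0)
  d465 <- normalize_dff(rec$F465, rec$sample_rate_hz)
  d405 <- normalize_dff(rec$F405, rec$sample_rate_hz)
  resid <- d465 - d405
  expect_lt(sum(resid^2) / sum(art^2), 0.01)
})

test_that("peak detection finds an inserted bump at its apex and only there", {
  dff <- rep(0, 2000)
  dff[990:1010] <- 0.05 * sin(seq(0, pi, length.out = 21))
  dff <- dff + rnorm(2000, 0, 1e-4)
  trace <- as_norm_trace(dff)
  pk <- detect_peaks(trace, threshold_sd = 2)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$time_s, trace$time_s[1000], tolerance = 0.02)
  # constant trace: no peaks, not an error
  expect_identical(nrow(detect_peaks(as_norm_trace(rep(0, 100)))), 0L)
})

test_that("excursion peaks equal a brute-force scan on white noise", {
  set.seed(99)
  dff <- rnorm(5000, 0, 0.01)
  trace <- as_norm_trace(dff)
  for (thr_sd in c(1, 2, 3)) {
    got <- detect_peaks(trace, threshold_sd = thr_sd, min_width_s = 0,
                        smooth_s = 0)
    want <- peak_oracle(dff, trace$time_s, thr_sd * trace$session_sd)
    expect_equal(got$time_s, want$time_s)
    expect_equal(got$amplitude, want$amplitude)
  }
  # the minimum-width rule also matches the oracle
  got <- detect_peaks(trace, 2, min_width_s = 0.05, smooth_s = 0)
  want <- peak_oracle(dff, trace$time_s, 2 * trace$session_sd,
                      min_width_n = 5L)
  expect_equal(got$time_s, want$time_s)
})

test_that("raising the threshold never adds peaks on transient traces", {
  # noise-free session with isolated transients (one per 20 s trial):
  # every excursion is a unimodal kernel, so the detected set shrinks
  # monotonically as the threshold rises (overlapping transients can
  # instead split into two excursions when the threshold passes the
  # saddle between them)
  s <- run_task_state_machine(task_config("I"),
                              agent_config(rng_seed = 12L), day = 4)
  rec <- generate_photometry(s$log, s$truth,
                             photometry_config(noise_sd = 0,
                                               artifact_rate_hz = 0))$recording
  trace <- process_recording(rec, sd_method = "sd")
  counts <- vapply(seq(0.25, 4, by = 0.25), function(th)
    nrow(detect_peaks(trace, th, min_width_s = 0)), numeric(1))
  expect_gt(counts[1], 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("peaks link to the nearest claiming behavioral event", {
  peaks <- data.frame(time_s = c(10.3, 25.0), amplitude = c(0.05, 0.04),
                      threshold = 0.01)
  behavior <- data.frame(time_s = c(10, 18), kind = c("lever_press", "lick_bout_onset"),
                         trial_idx = c(1L, 2L))
  linked <- link_peaks_to_behavior(peaks, behavior, association_window_s = 2)
  expect_identical(linked$linked_kind, c("lever_press", NA))
  expect_equal(linked$lag_s, c(0.3, NA))
  # earlier event wins a contested peak; each event claims at most one
  behavior2 <- data.frame(time_s = c(9.9, 10.0), kind = c("a", "b"),
                          trial_idx = 1:2)
  linked2 <- link_peaks_to_behavior(peaks[1, ], behavior2, 2)
  expect_identical(linked2$linked_kind, "a")
})

test_that("peri-event rows reproduce identical trials and flag short windows", {
  # two identical synthetic trials: mean equals each row
  tones <- c(10, 30)
  lines <- as.vector(rbind(sprintf("%.4f\ttone_on\t", tones),
                           sprintf("%.4f\ttone_off\t", tones + 5)))
  log <- log_from_lines(lines, phase = "I")
  seg <- classify_trials(segment_trials(log))
  t <- seq(0, 50, by = 0.01)
  burst <- function(t0) 0.05 * exp(-(t - t0)^2 / 0.1) * (t >= t0 - 2)
  dff <- burst(11) + burst(31)
  trace <- isosbestic_subtract(dff, rep(0, length(t)), t, 100)
  pem <- build_peri_event_matrix(trace, seg, "tone_on", pre_s = 2, post_s = 8)
  expect_identical(dim(pem$mat), c(2L, 1000L))
  expect_equal(pem$mat[1, ], pem$mat[2, ], tolerance = 1e-9)
  gm <- peri_event_group_means(pem)
  expect_equal(gm$mean[gm$outcome == "no_licks"], pem$mat[1, ],
               ignore_attr = TRUE)
  # a window that starts before the recording is flagged incomplete
  pem2 <- build_peri_event_matrix(trace, seg, "tone_on", pre_s = 15,
                                  post_s = 2)
  expect_true(pem2$incomplete[1])
  expect_false(pem2$incomplete[2])
})

test_that("windowed amplitude takes the in-window maximum per trial", {
  pem <- structure(list(
    mat = rbind(seq(0, 1, length.out = 100), rep(0, 100)),
    time_s = seq(0, 9.9, by = 0.1), outcome = c("rewarded", "no_licks"),
    trial_idx = 1:2, incomplete = c(FALSE, FALSE), align_on = "tone_on"),
    class = "peri_event_matrix")
  amp <- window_peak_amplitude(pem, c(0, 2))
  # monotone increasing row: the last bin before 2 s wins
  expect_equal(amp$amplitude[1], pem$mat[1, 20])
  expect_equal(amp$amplitude[2], 0)
  expect_error(window_peak_amplitude(pem, c(5, 20)), "span")
})

test_that("transients are recovered and attributed to the right behavior", {
  ps <- processed_session("II", day = 4, agent_seed = 21L)
  det <- recovered_amplitudes(ps$ses$truth, ps$peaks)
  expect_gte(mean(!is.na(det)), 0.85)
  gen <- ps$ses$truth$transients$amplitude
  expect_lt(max(abs(det - gen), na.rm = TRUE), 0.02)
})

test_that("photometry recordings round-trip and reject bad files", {
  s <- run_task_state_machine(task_config("I"),
                              agent_config(rng_seed = 2L), day = 1)
  rec <- generate_photometry(s$log, s$truth)$recording
  path <- withr::local_tempfile(fileext = ".csv")
  write_photometry(rec, path)
  back <- read_photometry(path)
  expect_equal(back$time_s, rec$time_s, tolerance = 1e-9)
  expect_equal(back$F465, rec$F465, tolerance = 1e-5)
  expect_identical(back$sample_rate_hz, rec$sample_rate_hz)
  # one-sample file: too short to normalize
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# mouse=a", "time_s,F405,F465", "0,1,1"), p2)
  expect_error(read_photometry(p2), "too short")
  # jitter within tolerance is accepted with a warning
  p3 <- withr::local_tempfile(fileext = ".csv")
  set.seed(8)
  tj <- seq(0, 5, by = 0.01) + runif(501, 0, 1e-5)
  writeLines(c("# mouse=a",
               "time_s,F405,F465",
               sprintf("%.7f,%.3f,%.3f", tj, 80 + tj, 100 + tj)), p3)
  expect_warning(rec3 <- read_photometry(p3), "jitter")
  expect_identical(length(rec3$F465), 501L)
})

test_that("linked-peak amplitudes aggregate by day with SEM", {
  lp <- data.frame(amplitude = c(0.05, 0.07, 0.02),
                   linked_kind = c("lever_press", "lever_press", NA),
                   day = c(1, 1, 1))
  tab <- peak_amplitude_by_day(lp)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$mean_amplitude, 0.06)
  expect_equal(tab$sem, stats::sd(c(0.05, 0.07)) / sqrt(2))
  # single peak: SEM missing
  tab1 <- peak_amplitude_by_day(lp[1, ])
  expect_true(is.na(tab1$sem))
})
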