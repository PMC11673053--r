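test_that("learning schedule follows the exponential relaxation exactly", {
  agent <- agent_config(latency_init_s = 8, latency_asymptote_s = 2,
                        learning_tau_days = 2)
  # day 1: exp(0) = 1, so the latency is the initial value exactly
  expect_identical(learning_schedule(agent, 1)$expected_latency_s, 8)
  # closed form at day 3: asymptote + (init - asymptote) * exp(-1)
  expect_equal(learning_schedule(agent, 3)$expected_latency_s,
               2 + 6 * exp(-1), tolerance = 1e-12)
  # large-day limit reaches the asymptote within 1%
  expect_equal(learning_schedule(agent, 100)$expected_latency_s, 2,
               tolerance = 0.01)
  # monotone: latency non-increasing, engagement non-decreasing in day
  lat <- vapply(1:12, function(d)
    learning_schedule(agent, d)$expected_latency_s, numeric(1))
  eng <- vapply(1:12, function(d)
    learning_schedule(agent, d)$engage_prob, numeric(1))
  expect_true(all(diff(lat) <= 0))
  expect_true(all(diff(eng) >= 0))
  expect_error(learning_schedule(agent, 0), "day")
  expect_error(agent_config(learning_tau_days = 0), "learning_tau_days")
})

test_that("a deterministic fully engaged agent is rewarded on every trial", {
  task <- task_config("I", trials_per_test = c(5L, 5L))
  s <- run_task_state_machine(task, deterministic_agent(latency = 1),
                              day = 1)
  ev <- s$log$events
  tone_on <- ev$time_s[ev$event == "tone_on"]
  expect_length(tone_on, 5L)
  expect_identical(s$truth$trials$outcome, rep("rewarded", 5L))
  # contingency forces >= 1 reward per trial; first lick 1 s after tone
  for (t0 in tone_on) {
    in_trial <- ev$time_s >= t0 & ev$time_s < t0 + 20
    expect_gte(sum(ev$event == "reward_delivery" & in_trial), 1L)
    first_lick <- min(ev$time_s[ev$event == "lick" & in_trial])
    expect_equal(first_lick - t0, 1, tolerance = 1e-4)
  }
})

test_that("an agent that never presses produces tones but no presses or rewards", {
  task <- task_config("III")
  s <- run_task_state_machine(task, inactive_agent(), day = 1)
  ev <- s$log$events
  expect_gt(sum(ev$event == "tone_on"), 0L)
  expect_identical(sum(ev$event == "lever_press"), 0L)
  expect_identical(sum(ev$event == "reward_delivery"), 0L)
  expect_true(all(s$truth$trials$outcome == "no_presses"))
})

test_that("free-operant trial count matches an independent scan of the log", {
  for (seed in 1:4) {
    task <- task_config("II")
    s <- run_task_state_machine(task, agent_config(rng_seed = seed),
                                day = 3)
    presses <- s$log$events$time_s[s$log$events$event == "lever_press"]
    # brute-force oracle: count presses outside any open 10 s trial window
    n_oracle <- 0L; open_until <- -Inf
    for (p in presses) {
      if (p >= open_until) {
        n_oracle <- n_oracle + 1L
        open_until <- p + task$trial_duration_s
      }
    }
    expect_identical(nrow(s$truth$trials), n_oracle)
    expect_identical(nrow(segment_trials(s$log, task)$trials), n_oracle)
  }
})

test_that("every generated reward satisfies the phase contingency on replay", {
  for (phase in c("I", "II", "III")) {
    task <- task_config(phase)
    for (seed in 1:5) {
      s <- run_task_state_machine(task, agent_config(rng_seed = seed),
                                  day = 1 + (seed %% task$days))
      expect_identical(check_contingency(s$log, task)$n_violations, 0L)
    }
  }
})

test_that("identical seeds reproduce byte-identical session files", {
  task <- task_config("I", trials_per_test = c(5L, 5L))
  agent <- agent_config(rng_seed = 11L)
  photo <- photometry_config(rng_seed = 13L)
  dirs <- file.path(withr::local_tempdir(), c("a", "b"))
  for (d in dirs) {
    ses <- simulate_session(task, agent, photo, day = 2)
    write_session(ses$log, ses$recording, NULL, ses$truth, d)
  }
  for (f in c("events.tsv", "photometry.csv", "truth_transients.csv",
              "truth_trials.csv")) {
    expect_identical(unname(tools::md5sum(file.path(dirs[1], f))),
                     unname(tools::md5sum(file.path(dirs[2], f))))
  }
})

test_that("with all stochastic terms off the 465 channel is pure bleached baseline", {
  task <- task_config("I")
  s <- run_task_state_machine(task, inactive_agent(), day = 1)
  cfg <- photometry_config(noise_sd = 0, artifact_rate_hz = 0)
  rec <- generate_photometry(s$log, s$truth, cfg)$recording
  expect_equal(rec$F465,
               cfg$baseline_F465 * exp(-rec$time_s / cfg$bleach_tau_s),
               tolerance = 1e-12)
})

test_that("a single noise-free transient peaks where dense kernel evaluation says", {
  task <- task_config("I", trials_per_test = c(1L, 1L))
  s <- run_task_state_machine(task, deterministic_agent(latency = 1),
                              day = 1)
  cfg <- photometry_config(noise_sd = 0, artifact_rate_hz = 0,
                           consumption_dip_amp = 0)
  out <- generate_photometry(s$log, s$truth, cfg)
  rec <- out$recording
  detrended <- rec$F465 / (cfg$baseline_F465 *
                             exp(-rec$time_s / cfg$bleach_tau_s)) - 1
  t_onset <- out$truth$transients$time_s[1]
  # oracle: dense numerical argmax of the double-exponential kernel
  tg <- seq(0, 5, by = 1e-4)
  kern <- (1 - exp(-tg / cfg$tau_rise_s)) * exp(-tg / cfg$tau_decay_s)
  t_peak_oracle <- t_onset + tg[which.max(kern)]
  t_peak_sim <- rec$time_s[which.max(detrended)]
  expect_equal(t_peak_sim, t_peak_oracle,
               tolerance = 1.5 / cfg$sample_rate_hz)
  expect_equal(max(detrended), cfg$transient_amp_rewarded, tolerance = 0.01)
})

test_that("ground-truth transients all lie within the session span", {
  for (phase in c("I", "II", "III")) {
    s <- run_task_state_machine(task_config(phase),
                                agent_config(rng_seed = 3L), day = 2)
    span <- range(s$log$events$time_s)
    tt <- s$truth$transients$time_s
    expect_true(all(tt >= span[1] & tt <= span[2]))
  }
})

test_that("pose track has one frame per video frame and stays in the box", {
  task <- task_config("I", trials_per_test = c(5L, 5L))
  s <- run_task_state_machine(task, deterministic_agent(), day = 1)
  pose <- generate_pose_track(s$log, task, deterministic_agent(),
                              frame_rate_hz = 30)
  dur <- max(s$log$events$time_s) + 5
  n_frames <- length(unique(pose$data$frame))
  expect_equal(n_frames, floor(dur * 30))
  geom <- task$geometry
  expect_true(all(pose$data$x >= 0 & pose$data$x <= geom$width_mm))
  expect_true(all(pose$data$y >= 0 & pose$data$y <= geom$height_mm))
})

test_that("invalid configurations are rejected", {
  expect_error(task_config("I", tone_duration_s = 0), "durations")
  expect_error(task_config("I", trials_per_test = c(0L, 5L)),
               "trials_per_test")
  expect_error(agent_config(engage_prob_init = 1.2), "probabilities")
  expect_error(agent_config(latency_init_s = 1, latency_asymptote_s = 2),
               "asymptote")
  expect_error(photometry_config(tau_rise_s = 1, tau_decay_s = 0.5),
               "tau_rise")
  expect_error(run_task_state_machine(task_config("I"), agent_config(),
                                      day = 99), "day")
})
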