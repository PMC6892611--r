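test_that("reaction-time sampling honours the configured distribution", {
  params <- default_rt_params()
  # degenerate configuration: timeout probability 1 always times out
  p1 <- default_rt_params()
  p1$control$unsuppressed$p_timeout <- 1
  set.seed(5)
  expect_true(all(is.na(replicate(20,
    sample_reaction_time("control", FALSE, p1)))))
  # unknown regime is a configuration error
  expect_error(sample_reaction_time("sham", TRUE), "unknown regime")
  # seeded draws are reproducible
  set.seed(9)
  a <- replicate(10, sample_reaction_time("recovered", TRUE))
  set.seed(9)
  b <- replicate(10, sample_reaction_time("recovered", TRUE))
  expect_identical(a, b)
  # Monte-Carlo fraction below 1 s matches the analytic CDF within 2 points
  set.seed(1)
  draws <- replicate(10000, sample_reaction_time("first_day", TRUE))
  frac <- mean(!is.na(draws) & draws < 1)
  expect_lt(abs(frac - rt_prob_below(params$first_day$suppressed, 1)), 0.02)
  expect_lt(abs(rt_prob_below(params$first_day$suppressed, 1) - 0.071),
            0.005)
})

test_that("regimes separate: first-day suppression blocks fast responses", {
  set.seed(2)
  fd <- replicate(1500, sample_reaction_time("first_day", TRUE))
  rc <- replicate(1500, sample_reaction_time("recovered", TRUE))
  expect_lt(mean(!is.na(fd) & fd < 1), 0.10)
  expect_gt(mean(!is.na(rc) & rc < 1), 0.40)
})

test_that("a noise-free trial holds fixation then jumps past the threshold", {
  cfg <- sim_config(n_trials = 1, regime = "control", seed = 4,
                    p_temporal_target = 1, noise_sd_deg = 0,
                    drift_amplitude_deg = 0)
  # force a completed trial
  cfg$rt_params$control$unsuppressed$p_timeout <- 0
  s <- simulate_behavior(cfg)
  tr <- s$schedule
  expect_equal(nrow(tr), 1)
  expect_false(tr$timeout)
  pre <- s$eye_trace$position_deg[s$eye_trace$time_s <= tr$target_onset_s]
  expect_true(all(abs(pre) <= 2.5))
  post_end <- tr$true_onset_s + tr$true_duration_s
  at_target <- s$eye_trace$position_deg[
    s$eye_trace$time_s >= post_end &
      s$eye_trace$time_s <= post_end + 0.2]
  expect_true(all(at_target > 5))
  expect_equal(tr$true_rt_s, tr$true_onset_s - tr$target_onset_s)
})

test_that("an empty session yields an empty schedule and a flat trace", {
  cfg <- sim_config(n_trials = 0, regime = "control", seed = 1,
                    noise_sd_deg = 0, drift_amplitude_deg = 0)
  s <- simulate_behavior(cfg)
  expect_equal(nrow(s$schedule), 0)
  expect_equal(nrow(s$truth_saccades), 0)
  expect_true(all(s$eye_trace$position_deg == 0))
})

test_that("sessions are deterministic given (config, seed)", {
  cfg <- sim_config(n_trials = 12, regime = "first_day", seed = 33)
  s1 <- simulate_behavior(cfg)
  s2 <- simulate_behavior(cfg)
  expect_identical(s1$eye_trace, s2$eye_trace)
  expect_identical(s1$schedule, s2$schedule)
  # serialized forms are byte-identical
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("injected saccades respect the detection margins", {
  cfg <- sim_config(n_trials = 30, regime = "recovered", seed = 8)
  s <- simulate_behavior(cfg)
  expect_true(all(s$truth_saccades$amplitude_deg >= 6))
  # minimum-jerk peak speed is 1.875 * amplitude / duration
  done <- s$schedule[!s$schedule$timeout, ]
  peak <- 1.875 * abs(done$true_amplitude_deg) / (done$true_duration_s * 1000)
  expect_true(all(peak >= 0.2))
  # every completed trial has exactly one injected saccade after its onset
  expect_equal(nrow(s$truth_saccades), sum(!s$schedule$timeout))
  expect_true(all(s$truth_saccades$onset_s >
                    done$target_onset_s[match(s$truth_saccades$trial_id,
                                              done$trial_id)]))
  # trials do not overlap
  expect_true(all(diff(s$schedule$fix_start_s) > 0))
  expect_true(all(utils::head(s$schedule$trial_end_s, -1) <=
                    utils::tail(s$schedule$fix_start_s, -1) + 1e-9))
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(n_trials = 10, p_temporal_target = 1.5),
               "probabilities")
  expect_error(sim_config(n_trials = 10, sampling_rate_eye = 50),
               "undersamples")
  expect_error(sim_config(n_trials = 10, fixation_hold_ms = c(1000, 750)),
               "interval")
})
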