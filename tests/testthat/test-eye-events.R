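test_that("speed of a linear ramp and a constant trace is exact", {
  t <- seq(0, 1, by = 1 / 500)
  ramp <- eye_trace(t, t * 1)  # 1 deg/s
  v <- compute_speed(ramp, smooth_window_samples = 1L)
  expect_equal(v, rep(0.001, length(t)), tolerance = 1e-12)
  flat <- eye_trace(t, rep(2, length(t)))
  expect_equal(compute_speed(flat), rep(0, length(t)))
  # interior samples are exact under smoothing too (ramp is linear)
  v5 <- compute_speed(ramp, smooth_window_samples = 5L)
  expect_equal(v5[4:(length(t) - 3)], rep(0.001, length(t) - 6),
               tolerance = 1e-12)
  # window 1 is the identity smoother: matches a raw central difference
  noisy <- eye_trace(t, sin(4 * pi * t))
  v1 <- compute_speed(noisy, 1L)
  expect_equal(v1[50], (noisy$position_deg[51] - noisy$position_deg[49]) /
                 (2 * 2), tolerance = 1e-12)
  expect_error(compute_speed(ramp, 4L), "odd")
  expect_error(compute_speed(eye_trace(t[1:3], c(0, 0, 0)), 5L), "shorter")
})

test_that("trace validation enforces the uniform-grid contract", {
  expect_error(eye_trace(c(0, 0.002, 0.003), c(0, 0, 0)), "uniform")
  expect_error(eye_trace(c(0, -1), c(0, 0)), "increasing")
  expect_error(eye_trace(c(0, 0.002), c(0, NA)), "missing")
})

test_that("saccade detection applies amplitude and speed thresholds", {
  # 8 degrees in 20 ms (peak 0.75 deg/ms): exactly one temporal event
  tr <- make_step_trace(8, onset_s = 1, dur_s = 0.02)
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "temporal")
  expect_equal(ev$amplitude_deg, 8, tolerance = 0.05)
  expect_lt(abs(ev$onset_s - 1), 0.006)
  expect_gt(ev$peak_speed_deg_per_ms, 0.1)
  # rapid but small (3 degrees): rejected by the amplitude threshold
  expect_equal(nrow(detect_saccades(make_step_trace(3, 1, 0.02))), 0)
  # large but slow (8 degrees over 1 s, 0.008 deg/ms): below speed threshold
  expect_equal(nrow(detect_saccades(make_step_trace(8, 0.4, 1))), 0)
  # nasal direction from the displacement sign
  expect_equal(detect_saccades(make_step_trace(-7, 1, 0.02))$direction,
               "nasal")
})

test_that("events split by a brief speed dip are merged", {
  # two 4-degree steps 10 ms apart: one 8-degree saccade after merging
  t <- seq(0, 2, by = 1 / 500)
  tau1 <- pmin(pmax((t - 1.00) / 0.015, 0), 1)
  tau2 <- pmin(pmax((t - 1.025) / 0.015, 0), 1)
  mj <- function(x) 10 * x^3 - 15 * x^4 + 6 * x^5
  tr <- eye_trace(t, 4 * mj(tau1) + 4 * mj(tau2))
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_deg, 8, tolerance = 0.1)
  # with merging disabled the two halves fail the 5-degree threshold
  expect_equal(nrow(detect_saccades(tr, merge_gap_ms = 0)), 0)
})

test_that("raising the amplitude threshold never adds events", {
  cfg <- sim_config(n_trials = 15, regime = "recovered", seed = 21)
  s <- simulate_behavior(cfg)
  counts <- vapply(c(0, 2, 5, 6.5, 8, 12), function(a)
    nrow(detect_saccades(s$eye_trace, amp_min_deg = a)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detector recovers generator ground truth exactly", {
  cfg <- sim_config(n_trials = 40, regime = "control", seed = 14)
  s <- simulate_behavior(cfg)
  ev <- detect_saccades(s$eye_trace)
  expect_equal(nrow(ev), nrow(s$truth_saccades))  # recall = precision = 1
  expect_true(all(abs(ev$onset_s - s$truth_saccades$onset_s) <= 0.006))
  expect_identical(ev$direction, s$truth_saccades$direction)
})

test_that("condition mapping flips with the hemisphere label and only then", {
  sides <- c("nasal", "temporal", "temporal")
  right <- movement_condition(sides, "right")
  left <- movement_condition(sides, "left")
  expect_equal(right, c("ipsiversive", "contraversive", "contraversive"))
  expect_equal(left, c("contraversive", "ipsiversive", "ipsiversive"))
  # involution: flipping twice restores the original labels
  expect_identical(right, movement_condition(sides, "right"))
})

test_that("trial scoring assigns outcomes per the task rules", {
  mj <- function(x) 10 * x^3 - 15 * x^4 + 6 * x^5
  t <- seq(0, 14, by = 1 / 500)
  sched <- tibble::tibble(trial_id = 1L, target_side = "temporal",
                          suppressed = FALSE, target_onset_s = 1)
  # qualifying saccade 1.2 s after target onset: correct, RT = 1.2 s
  tau <- pmin(pmax((t - 2.2) / 0.025, 0), 1)
  tr <- eye_trace(t, 7 * mj(tau))
  sc <- score_trials(tr, sched)
  expect_equal(sc$outcome, "correct")
  expect_equal(sc$reaction_time_s, 1.2, tolerance = 0.006)
  expect_equal(sc$condition, "contraversive")
  # nothing within 10 s and position in window: timeout, RT absent
  flat <- eye_trace(t, rep(0.5, length(t)))
  sc2 <- score_trials(flat, sched)
  expect_equal(sc2$outcome, "timeout")
  expect_true(is.na(sc2$reaction_time_s))
  # first rapid movement opposite to the target: wrong_direction
  tr3 <- eye_trace(t, -7 * mj(tau))
  expect_equal(score_trials(tr3, sched)$outcome, "wrong_direction")
  # rapid movement in the right direction but below 5 degrees
  tr4 <- eye_trace(t, 3.5 * mj(tau))
  expect_equal(score_trials(tr4, sched)$outcome, "small_amplitude")
  # slow drift out of the fixation window with no rapid movement
  drift <- eye_trace(t, pmin(pmax((t - 2) / 4, 0), 1) * 4)
  expect_equal(score_trials(drift, sched)$outcome, "drift_out")
})

test_that("scored reaction times match generator ground truth", {
  cfg <- sim_config(n_trials = 30, regime = "first_day", seed = 6)
  s <- simulate_behavior(cfg)
  sc <- score_trials(s$eye_trace, s$schedule)
  done <- !s$schedule$timeout
  expect_identical(sc$outcome == "correct", done)
  expect_true(all(abs(sc$reaction_time_s[done] -
                        s$schedule$true_rt_s[done]) <= 0.006))
  expect_error(score_trials(s$eye_trace, s$schedule[c(2, 1), ]),
               "increasing")
})
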