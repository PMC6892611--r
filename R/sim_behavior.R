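#' Draw one reaction time (or timeout) for a regime and condition
#'
#' Latency model: with probability `p_timeout` the trial times out; otherwise
#' the latency is `shift + X` with `X` lognormal. Draws at or beyond the
#' response window are also timeouts. Uses the current RNG state; seed it
#' with [set.seed()] (or let [simulate_behavior()] manage streams).
#'
#' @param regime regime name present in `rt_params`.
#' @param suppressed logical, whether the trial carries the suppression flag.
#' @param rt_params nested parameter list, see [default_rt_params()].
#' @param response_window_s response window in seconds.
#' @return A latency in seconds, or `NA_real_` for a timeout.
#' @export
sample_reaction_time <- function(regime, suppressed,
                                 rt_params = default_rt_params(),
                                 response_window_s = 10) {
  if (!regime %in% names(rt_params))
    stop_config("unknown regime '%s'", regime)
  stopifnot(is_flag(suppressed))
  p <- rt_params[[regime]][[if (suppressed) "suppressed" else "unsuppressed"]]
  if (is.null(p))
    stop_config("regime '%s' has no parameters for this condition", regime)
  # both branches consume RNG draws so the stream advances identically
  u <- runif(1)
  x <- p$shift + rlnorm(1, p$meanlog, p$sdlog)
  if (u < p$p_timeout || x >= response_window_s) return(NA_real_)
  x
}

# minimum-jerk position profile on [0, 1]: smooth, zero velocity at both
# ends, peak speed 1.875 * amplitude / duration at the midpoint
minimum_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Simulate a behavioral session: eye trace, schedule and ground truth
#'
#' Realizes the task state machine on a uniform grid at the configured eye
#' sampling rate. Each trial is: settled fixation inside the fixation window,
#' a hold drawn uniformly from the configured interval, target onset, and —
#' unless the trial times out — a minimum-jerk response saccade toward the
#' target side at the sampled latency, followed by a hold at the target and a
#' slow sub-threshold drift back to fixation. Additive Gaussian noise and a
#' slow sinusoidal drift are superimposed on the whole trace. The returned
#' schedule records ground truth (true movement onset, latency, injected
#' saccade geometry), so detector recall/precision can be asserted exactly.
#'
#' @param config a [sim_config()].
#' @return An object of class `session_data`: list with `eye_trace` (tibble
#'   `time_s`, `position_deg`), `schedule` (tibble, one row per trial) and
#'   `truth_saccades` (tibble of injected response saccades).
#' @export
simulate_behavior <- function(config) {
  validate_sim_config(config)
  fs <- config$sampling_rate_eye
  dt <- 1 / fs
  with_seed(substream_seed(config$seed, "behavior"), {
    n <- config$n_trials
    sched <- vector("list", n)
    segs <- list()
    t_cur <- config$pre_fix_s  # settled fixation from t = 0
    for (i in seq_len(n)) {
      side <- if (runif(1) < config$p_temporal_target) "temporal" else "nasal"
      suppressed <- runif(1) < config$p_suppression_trial
      hold_s <- runif(1, config$fixation_hold_ms[1],
                      config$fixation_hold_ms[2]) / 1000
      target_onset <- t_cur + hold_s
      rt <- sample_reaction_time(config$regime, suppressed, config$rt_params,
                                 config$response_window_s)
      if (is.na(rt)) {
        onset <- NA_real_
        amp <- NA_real_
        dur <- NA_real_
        trial_end <- target_onset + config$response_window_s +
          config$pre_fix_s
      } else {
        onset <- target_onset + rt
        amp <- runif(1, config$saccade_amplitude_deg[1],
                     config$saccade_amplitude_deg[2])
        if (side == "nasal") amp <- -amp
        dur <- runif(1, config$saccade_duration_ms[1],
                     config$saccade_duration_ms[2]) / 1000
        segs[[length(segs) + 1L]] <-
          list(onset = onset, dur = dur, amp = amp)
        trial_end <- onset + dur + config$post_move_hold_s +
          config$return_drift_s + config$pre_fix_s
      }
      sched[[i]] <- tibble::tibble(
        trial_id = i, target_side = side, suppressed = suppressed,
        fix_start_s = t_cur, target_onset_s = target_onset,
        true_onset_s = onset, true_rt_s = rt, timeout = is.na(rt),
        true_amplitude_deg = amp, true_duration_s = dur,
        trial_end_s = trial_end)
      t_cur <- trial_end
    }
    schedule <- if (n > 0) dplyr::bind_rows(sched) else empty_schedule()
    session_end <- t_cur + config$pre_fix_s
    time_s <- seq(0, session_end, by = dt)
    pos <- numeric(length(time_s))
    for (s in segs) {
      # saccade displacement, then hold at target, then slow linear return;
      # outside [onset, return end] the net contribution is exactly zero
      t_ret0 <- s$onset + s$dur + config$post_move_hold_s
      t_ret1 <- t_ret0 + config$return_drift_s
      i0 <- findInterval(s$onset, time_s) + 1L
      i1 <- min(findInterval(t_ret1, time_s) + 1L, length(time_s))
      if (i1 < i0) next
      tt <- time_s[i0:i1]
      move <- s$amp * minimum_jerk((tt - s$onset) / s$dur)
      ret <- pmin(pmax((tt - t_ret0) / config$return_drift_s, 0), 1)
      pos[i0:i1] <- pos[i0:i1] + move - s$amp * ret
    }
    if (config$drift_amplitude_deg > 0) {
      pos <- pos + config$drift_amplitude_deg *
        sin(2 * pi * time_s / config$drift_period_s)
    }
    if (config$noise_sd_deg > 0) {
      pos <- pos + rnorm(length(pos), 0, config$noise_sd_deg)
    }
    truth <- schedule[!schedule$timeout, ]
    truth_saccades <- tibble::tibble(
      trial_id = truth$trial_id,
      onset_s = truth$true_onset_s,
      offset_s = truth$true_onset_s + truth$true_duration_s,
      amplitude_deg = abs(truth$true_amplitude_deg),
      direction = ifelse(truth$true_amplitude_deg > 0, "temporal", "nasal"))
    structure(list(
      eye_trace = eye_trace(time_s, pos),
      schedule = schedule,
      truth_saccades = truth_saccades,
      config = config), class = "session_data")
  })
}

empty_schedule <- function() {
  tibble::tibble(trial_id = integer(), target_side = character(),
                 suppressed = logical(), fix_start_s = numeric(),
                 target_onset_s = numeric(), true_onset_s = numeric(),
                 true_rt_s = numeric(), timeout = logical(),
                 true_amplitude_deg = numeric(), true_duration_s = numeric(),
                 trial_end_s = numeric())
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf(
    "<session_data> %d trials (%d completed), %.1f s trace at %g Hz\n",
    nrow(x$schedule), sum(!x$schedule$timeout),
    max(x$eye_trace$time_s), x$config$sampling_rate_eye))
  invisible(x)
}

#' Write the session artifacts as plain-text files
#'
#' Emits `eye_trace.csv` (time_s, position_deg), `schedule.csv` and
#' `truth_saccades.csv` into `dir`.
#'
#' @param session a `session_data` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("eye_trace.csv", "schedule.csv",
                            "truth_saccades.csv"))
  write.csv(session$eye_trace, paths[1], row.names = FALSE)
  write.csv(session$schedule, paths[2], row.names = FALSE)
  write.csv(session$truth_saccades, paths[3], row.names = FALSE)
  invisible(paths)
}
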