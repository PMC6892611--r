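#' Default reaction-time parameters per regime and suppression condition
#'
#' Latencies for completed trials follow a (optionally shifted) lognormal with
#' an explicit timeout probability per (regime, condition) cell. The defaults
#' are solved analytically so that the configured probability of a reaction
#' time below 1 s and below 10 s, and the median of completed trials, match
#' the regime the cell emulates:
#'
#' * `first_day` suppressed: the 1 s suppression window almost abolishes fast
#'   responses (P(RT < 1 s) about 7%, median 1.76 s);
#' * `first_day` unsuppressed: intact behavior (about 40% below 1 s);
#' * `recovered`: condition-matched — suppressed and unsuppressed trials share
#'   one distribution with roughly 46% of latencies below 1 s, emulating the
#'   regained capability to move during the suppression window;
#' * `bilateral`: suppressing the second hemisphere reinstates the impairment
#'   (about 19% below 1 s suppressed vs 67% unsuppressed);
#' * `control`: no optogenetic effect in either condition.
#'
#' @return Nested list `rt_params[[regime]][[condition]]` with fields
#'   `shift` (s), `meanlog`, `sdlog` (log-seconds) and `p_timeout`.
#' @export
default_rt_params <- function() {
  cell <- function(meanlog, sdlog, p_timeout, shift = 0) {
    list(shift = shift, meanlog = meanlog, sdlog = sdlog,
         p_timeout = p_timeout)
  }
  intact <- cell(meanlog = log(1.09), sdlog = 1.0, p_timeout = 0.139)
  recov <- cell(meanlog = 0, sdlog = 1.2, p_timeout = 0.071)
  list(
    first_day = list(suppressed = cell(log(1.76), 0.43, 0.244),
                     unsuppressed = intact),
    recovered = list(suppressed = recov, unsuppressed = recov),
    bilateral = list(suppressed = cell(log(1.27), 0.35, 0.054),
                     unsuppressed = cell(log(0.45), 1.7, 0.023)),
    control = list(suppressed = intact, unsuppressed = intact)
  )
}

#' Configuration for a simulated behavioral session
#'
#' Holds the task constants (fixation window, hold interval, response window,
#' suppression duration), the trial schedule parameters, the regime-dependent
#' reaction-time model and the trace-generation parameters. Laser pulse
#' settings and LED powers are recorded as metadata only; they never enter any
#' computation.
#'
#' @param n_trials number of trials in the session.
#' @param regime one of `"first_day"`, `"recovered"`, `"bilateral"`,
#'   `"control"`; selects the reaction-time distributions and the default
#'   suppression probability.
#' @param seed integer master seed for the session.
#' @param p_temporal_target probability that a trial's target is on the
#'   temporal side.
#' @param p_suppression_trial probability that a trial carries the optogenetic
#'   suppression flag. Defaults to 0.3 on first-day and bilateral regimes, 0.5
#'   on recovered, and 0 for controls.
#' @param sampling_rate_eye eye-trace sampling rate, Hz.
#' @param frame_rate imaging frame rate, Hz.
#' @param fixation_window_deg half-width of the fixation window, degrees.
#' @param fixation_hold_ms two-element interval (ms) for the required hold.
#' @param response_window_s response window after target onset, seconds.
#' @param suppression_duration_s duration of the suppression window, seconds.
#' @param rt_params nested latency parameters, see [default_rt_params()].
#' @param hemisphere hemisphere under study (`"right"` or `"left"`); maps
#'   target sides to contraversive/ipsiversive conditions.
#' @param noise_sd_deg s.d. of additive Gaussian positional noise, degrees.
#' @param drift_amplitude_deg amplitude of the slow sinusoidal drift, degrees.
#' @param drift_period_s period of the slow drift, seconds.
#' @param saccade_amplitude_deg two-element range for injected response
#'   saccade amplitudes (degrees); the default 6–9 keeps a safety margin above
#'   the 5 degree detection threshold.
#' @param saccade_duration_ms two-element range of saccade durations (ms).
#' @param pre_fix_s settled fixation time before the hold starts, seconds.
#' @param post_move_hold_s hold at the target after the response, seconds.
#' @param return_drift_s duration of the slow sub-threshold drift back to the
#'   fixation position, seconds.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_trials,
                       regime = c("control", "first_day", "recovered",
                                  "bilateral"),
                       seed = 1L,
                       p_temporal_target = 0.5,
                       p_suppression_trial = NULL,
                       sampling_rate_eye = 500,
                       frame_rate = 6,
                       fixation_window_deg = 2.5,
                       fixation_hold_ms = c(750, 1000),
                       response_window_s = 10,
                       suppression_duration_s = 1,
                       rt_params = default_rt_params(),
                       hemisphere = c("right", "left"),
                       noise_sd_deg = 0.1,
                       drift_amplitude_deg = 0.3,
                       drift_period_s = 8,
                       saccade_amplitude_deg = c(6, 9),
                       saccade_duration_ms = c(20, 30),
                       pre_fix_s = 0.5,
                       post_move_hold_s = 0.5,
                       return_drift_s = 1.0) {
  regime <- match.arg(regime)
  hemisphere <- match.arg(hemisphere)
  if (is.null(p_suppression_trial)) {
    p_suppression_trial <- switch(regime,
                                  first_day = 0.3, bilateral = 0.3,
                                  recovered = 0.5, control = 0)
  }
  cfg <- list(
    n_trials = as.integer(n_trials), regime = regime, seed = as.integer(seed),
    p_temporal_target = p_temporal_target,
    p_suppression_trial = p_suppression_trial,
    sampling_rate_eye = sampling_rate_eye, frame_rate = frame_rate,
    fixation_window_deg = fixation_window_deg,
    fixation_hold_ms = fixation_hold_ms,
    response_window_s = response_window_s,
    suppression_duration_s = suppression_duration_s,
    rt_params = rt_params, hemisphere = hemisphere,
    noise_sd_deg = noise_sd_deg,
    drift_amplitude_deg = drift_amplitude_deg,
    drift_period_s = drift_period_s,
    saccade_amplitude_deg = saccade_amplitude_deg,
    saccade_duration_ms = saccade_duration_ms,
    pre_fix_s = pre_fix_s, post_move_hold_s = post_move_hold_s,
    return_drift_s = return_drift_s,
    # acquisition metadata, echoed to reports, never used in computation
    metadata = list(led_power_uw = c(fix_idle = 260, fix_on = 470,
                                     fix_acquired = 500, target = 450),
                    laser_pulse_hz = 40, laser_pulse_width_ms = 2.5)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_number(cfg$n_trials) || cfg$n_trials < 0)
    stop_config("n_trials must be a non-negative count")
  if (!is_prob(cfg$p_temporal_target) || !is_prob(cfg$p_suppression_trial))
    stop_config("trial probabilities must lie in [0, 1]")
  for (f in c("sampling_rate_eye", "frame_rate", "fixation_window_deg",
              "response_window_s", "suppression_duration_s", "noise_sd_deg",
              "drift_period_s", "pre_fix_s", "post_move_hold_s",
              "return_drift_s")) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0)
      stop_config("%s must be a non-negative number", f)
  }
  for (f in c("sampling_rate_eye", "frame_rate", "response_window_s",
              "suppression_duration_s", "drift_period_s"))
    if (cfg[[f]] <= 0) stop_config("%s must be > 0", f)
  if (length(cfg$fixation_hold_ms) != 2L || diff(cfg$fixation_hold_ms) < 0 ||
      any(cfg$fixation_hold_ms <= 0))
    stop_config("fixation_hold_ms must be an increasing positive interval")
  # saccades occupy ~20-40 ms; the trace must resolve their velocity profile
  if (cfg$sampling_rate_eye < 2 * 1000 / min(cfg$saccade_duration_ms))
    stop_config("sampling_rate_eye undersamples the saccade bandwidth")
  if (!cfg$regime %in% names(cfg$rt_params))
    stop_config("regime '%s' missing from rt_params", cfg$regime)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d trials, regime '%s', seed %d\n  p(temporal)=%.2f, p(suppression)=%.2f, %g Hz eye / %g Hz frames\n",
    x$n_trials, x$regime, x$seed, x$p_temporal_target,
    x$p_suppression_trial, x$sampling_rate_eye, x$frame_rate))
  invisible(x)
}

#' Configured probability that a reaction time falls below a threshold
#'
#' Closed-form CDF of the latency model (lognormal completed-trial latencies
#' with an explicit timeout probability): timeouts never fall below any
#' threshold, so `P(RT < t) = (1 - p_timeout) * F_lognormal(t - shift)`.
#' Used as the analytic reference for Monte-Carlo checks of
#' [sample_reaction_time()].
#'
#' @param params one cell of `rt_params` (fields `shift`, `meanlog`, `sdlog`,
#'   `p_timeout`).
#' @param threshold_s threshold in seconds.
#' @return Probability over all trials (timeouts included in the denominator).
#' @export
rt_prob_below <- function(params, threshold_s) {
  stopifnot(is_number(threshold_s))
  if (threshold_s <= params$shift) return(0)
  (1 - params$p_timeout) *
    stats::plnorm(threshold_s - params$shift, params$meanlog, params$sdlog)
}
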