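#' Construct a validated eye-position trace
#'
#' @param time_s strictly increasing timestamps on a uniform grid, seconds.
#' @param position_deg azimuthal position of the tracked (left) eye in
#'   degrees; positive values are temporal.
#' @return A tibble of class `eye_trace` with columns `time_s`,
#'   `position_deg`.
#' @export
eye_trace <- function(time_s, position_deg) {
  stopifnot(is.numeric(time_s), is.numeric(position_deg),
            length(time_s) == length(position_deg))
  if (length(time_s) >= 2) {
    d <- diff(time_s)
    if (any(d <= 0)) stop_config("time_s must be strictly increasing")
    if (diff(range(d)) > 1e-9)
      stop_config("time_s must lie on a uniform grid (tolerance 1e-9 s)")
  }
  if (anyNA(position_deg) || any(!is.finite(position_deg)))
    stop_config("position_deg contains missing or non-finite samples")
  structure(tibble::tibble(time_s = time_s, position_deg = position_deg),
            class = c("eye_trace", class(tibble::tibble())))
}

trace_dt <- function(trace) {
  if (nrow(trace) < 2) stop_config("trace needs at least two samples")
  (trace$time_s[nrow(trace)] - trace$time_s[1]) / (nrow(trace) - 1)
}

# centered moving average with shrinking one-sided windows at the endpoints
moving_average <- function(x, window) {
  if (window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Eye speed in degrees per millisecond
#'
#' Smooths the position with a centered moving average, then differentiates
#' with central differences (one-sided at the endpoints). The default window
#' of 5 samples (10 ms at 500 Hz) suppresses tracker noise without blunting
#' 20–30 ms saccades.
#'
#' @param trace an [eye_trace()].
#' @param smooth_window_samples odd window length in samples; 1 disables
#'   smoothing.
#' @return Numeric speed series, deg/ms, same length as the trace.
#' @export
compute_speed <- function(trace, smooth_window_samples = 5L) {
  w <- as.integer(smooth_window_samples)
  if (w < 1L || w %% 2L == 0L)
    stop_config("smooth_window_samples must be odd and >= 1")
  if (nrow(trace) < max(w, 2L))
    stop_config("trace shorter than the smoothing window")
  dt_ms <- trace_dt(trace) * 1000
  p <- moving_average(trace$position_deg, w)
  n <- length(p)
  v <- numeric(n)
  v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt_ms)
  v[1] <- (p[2] - p[1]) / dt_ms
  v[n] <- (p[n] - p[n - 1]) / dt_ms
  v
}

#' Detect saccades by speed and amplitude thresholds
#'
#' Candidate events are maximal runs of samples whose absolute smoothed speed
#' exceeds `speed_min_deg_per_ms`; runs separated by less than `merge_gap_ms`
#' are merged (a mid-flight speed dip must not split one saccade in two).
#' Event amplitude is the net start-to-end displacement of the run — not the
#' path length — and events are kept only when it exceeds `amp_min_deg` in
#' absolute value. Both thresholds are strict inequalities.
#'
#' @param trace an [eye_trace()].
#' @param amp_min_deg minimum absolute amplitude, degrees (exclusive).
#' @param speed_min_deg_per_ms minimum absolute speed, deg/ms (exclusive).
#' @param merge_gap_ms sub-threshold gaps shorter than this are bridged.
#' @param smooth_window_samples passed to [compute_speed()].
#' @return Tibble with columns `onset_s`, `offset_s`, `amplitude_deg`
#'   (absolute), `peak_speed_deg_per_ms`, `direction` (`"temporal"` for
#'   positive displacement, `"nasal"` for negative).
#' @export
detect_saccades <- function(trace, amp_min_deg = 5,
                            speed_min_deg_per_ms = 0.1,
                            merge_gap_ms = 20,
                            smooth_window_samples = 5L) {
  v <- compute_speed(trace, smooth_window_samples)
  fast <- abs(v) > speed_min_deg_per_ms
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) return(empty_saccades())
  dt_ms <- trace_dt(trace) * 1000
  gap_samples <- merge_gap_ms / dt_ms
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      k <- nrow(merged)
      if (runs$start[i] - merged$end[k] < gap_samples) {
        merged$end[k] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  pos <- trace$position_deg
  amp <- pos[merged$end] - pos[merged$start]
  keep <- abs(amp) > amp_min_deg
  merged <- merged[keep, , drop = FALSE]
  amp <- amp[keep]
  if (nrow(merged) == 0) return(empty_saccades())
  peak <- vapply(seq_len(nrow(merged)), function(i)
    max(abs(v[merged$start[i]:merged$end[i]])), numeric(1))
  tibble::tibble(
    onset_s = trace$time_s[merged$start],
    offset_s = trace$time_s[merged$end],
    amplitude_deg = abs(amp),
    peak_speed_deg_per_ms = peak,
    direction = ifelse(amp > 0, "temporal", "nasal"))
}

empty_saccades <- function() {
  tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                 amplitude_deg = numeric(),
                 peak_speed_deg_per_ms = numeric(), direction = character())
}

#' Map target side to contraversive/ipsiversive condition
#'
#' The tracked left eye moves temporally (positive) when it moves away from
#' the right hemisphere; for a study of the right hemisphere, temporal-target
#' trials are therefore contraversive. Flipping the hemisphere label swaps
#' the two conditions and changes nothing else.
#'
#' @param target_side `"nasal"` or `"temporal"` (vectorized).
#' @param hemisphere hemisphere under study, `"right"` or `"left"`.
#' @return Character vector, `"contraversive"` or `"ipsiversive"`.
#' @export
movement_condition <- function(target_side, hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(all(target_side %in% c("nasal", "temporal")))
  contra_side <- if (hemisphere == "right") "temporal" else "nasal"
  ifelse(target_side == contra_side, "contraversive", "ipsiversive")
}

#' Score trials into outcomes with reaction times
#'
#' For each trial the first rapid movement after target onset decides the
#' outcome: `correct` when its direction matches the target and its amplitude
#' exceeds `amp_min_deg` within the response window (reaction time = movement
#' onset minus target onset); `wrong_direction` or `small_amplitude` for
#' disqualifying rapid movements; `drift_out` when the unsmoothed position
#' leaves the fixation window before any rapid movement; `timeout` when
#' nothing happens within the window. Rapid movements are detected once on
#' the whole trace with no amplitude floor, so sub-threshold rapid movements
#' disqualify a trial rather than being ignored.
#'
#' @param trace an [eye_trace()] spanning the schedule.
#' @param schedule tibble with at least `trial_id`, `target_side`,
#'   `suppressed`, `target_onset_s` (sorted, non-overlapping trials).
#' @param response_window_s response window, seconds.
#' @param fixation_window_deg half-width of the fixation window, degrees.
#' @param amp_min_deg,speed_min_deg_per_ms detection thresholds.
#' @param hemisphere hemisphere under study, for the condition column.
#' @param smooth_window_samples passed to [compute_speed()].
#' @return Tibble with one row per trial: `trial_id`, `target_side`,
#'   `condition`, `suppressed`, `target_onset_s`, `movement_onset_s`,
#'   `reaction_time_s`, `outcome`.
#' @export
score_trials <- function(trace, schedule,
                         response_window_s = 10,
                         fixation_window_deg = 2.5,
                         amp_min_deg = 5,
                         speed_min_deg_per_ms = 0.1,
                         hemisphere = c("right", "left"),
                         smooth_window_samples = 5L) {
  hemisphere <- match.arg(hemisphere)
  n <- nrow(schedule)
  if (n == 0) {
    return(tibble::tibble(trial_id = integer(), target_side = character(),
                          condition = character(), suppressed = logical(),
                          target_onset_s = numeric(),
                          movement_onset_s = numeric(),
                          reaction_time_s = numeric(), outcome = character()))
  }
  ons <- schedule$target_onset_s
  if (is.unsorted(ons, strictly = TRUE))
    stop_config("schedule target onsets must be strictly increasing")
  if (min(ons) < min(trace$time_s) || max(ons) > max(trace$time_s))
    stop_config("schedule times must lie within the trace")
  win_end <- pmin(ons + response_window_s,
                  c(ons[-1], Inf))  # truncate at the next trial
  if (any(win_end <= ons)) stop_config("overlapping trials in schedule")
  rapid <- detect_saccades(trace, amp_min_deg = 0,
                           speed_min_deg_per_ms = speed_min_deg_per_ms,
                           smooth_window_samples = smooth_window_samples)
  out <- character(n)
  move_on <- rep(NA_real_, n)
  rt <- rep(NA_real_, n)
  tvec <- trace$time_s
  pvec <- abs(trace$position_deg)
  for (i in seq_len(n)) {
    ev <- rapid[rapid$onset_s > ons[i] & rapid$onset_s <= win_end[i], ]
    first_ev_on <- if (nrow(ev) > 0) ev$onset_s[1] else Inf
    # first unsmoothed sample outside the fixation window, before any event
    i0 <- findInterval(ons[i], tvec) + 1L
    i1 <- findInterval(min(win_end[i], first_ev_on - 1e-12), tvec)
    idx <- if (i1 >= i0) which(pvec[i0:i1] > fixation_window_deg) else integer()
    if (length(idx) > 0) {
      out[i] <- "drift_out"
    } else if (nrow(ev) == 0) {
      out[i] <- "timeout"
    } else {
      e <- ev[1, ]
      if (e$direction != schedule$target_side[i]) {
        out[i] <- "wrong_direction"
      } else if (e$amplitude_deg <= amp_min_deg) {
        out[i] <- "small_amplitude"
      } else {
        out[i] <- "correct"
        move_on[i] <- e$onset_s
        rt[i] <- e$onset_s - ons[i]
      }
    }
  }
  tibble::tibble(
    trial_id = schedule$trial_id,
    target_side = schedule$target_side,
    condition = movement_condition(schedule$target_side, hemisphere),
    suppressed = schedule$suppressed,
    target_onset_s = ons,
    movement_onset_s = move_on,
    reaction_time_s = rt,
    outcome = out)
}
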