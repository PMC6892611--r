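# Independent brute-force oracles for the rank tests, plus small fixture
# builders shared across test files.

# Exhaustive signed-rank two-sided p: enumerate all 2^n sign assignments of
# the ranked absolute differences (zeros dropped first).
enum_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-12)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Exhaustive Mann-Whitney two-sided p: enumerate all C(nx+ny, nx)
# assignments of the pooled ranks to the first group.
enum_mann_whitney_p <- function(x, y) {
  nx <- length(x)
  pooled <- rank(c(x, y))
  u_obs <- sum(pooled[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(ii) sum(pooled[ii])) -
    nx * (nx + 1) / 2
  p_le <- mean(u_all <= u_obs + 1e-12)
  p_ge <- mean(u_all >= u_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# flat trace with an embedded minimum-jerk step: `amp` degrees traversed in
# `dur_s` seconds starting at `onset_s`
make_step_trace <- function(amp, onset_s, dur_s, total_s = 2, fs = 500,
                            noise_sd = 0) {
  t <- seq(0, total_s, by = 1 / fs)
  tau <- pmin(pmax((t - onset_s) / dur_s, 0), 1)
  p <- amp * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  if (noise_sd > 0) p <- p + rnorm(length(p), 0, noise_sd)
  eye_trace(t, p)
}

# regular-grid trial schedule with movement onsets on the imaging frame
# grid (frame_rate Hz), alternating target sides, no timeouts
make_grid_schedule <- function(n_trials, period_s = 5, onset_in_trial = 3,
                               frame_rate = 6) {
  start <- (seq_len(n_trials) - 1) * period_s
  onset <- round((start + onset_in_trial) * frame_rate) / frame_rate
  tibble::tibble(
    trial_id = seq_len(n_trials),
    target_side = rep_len(c("temporal", "nasal"), n_trials),
    suppressed = FALSE,
    fix_start_s = start,
    target_onset_s = start + 1.5,
    true_onset_s = onset,
    true_rt_s = onset - (start + 1.5),
    timeout = FALSE,
    trial_end_s = start + period_s - 0.2)
}
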