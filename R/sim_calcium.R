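#' Double-exponential calcium transient kernel
#'
#' Peak-normalized difference of exponentials,
#' `K(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / k_peak` for `t >= 0`,
#' 0 before onset. With the GCaMP-like defaults (rise 0.1 s, decay 0.6 s)
#' the peak sits [kernel_time_to_peak()] after transient onset.
#'
#' @param t time since transient onset, seconds (vectorized).
#' @param tau_rise_s,tau_decay_s time constants, seconds (`0 < rise < decay`).
#' @return Kernel values in `[0, 1]`, peak exactly 1.
#' @export
calcium_kernel <- function(t, tau_rise_s = 0.1, tau_decay_s = 0.6) {
  stopifnot(tau_rise_s > 0, tau_decay_s > tau_rise_s)
  tp <- kernel_time_to_peak(tau_rise_s, tau_decay_s)
  peak <- exp(-tp / tau_decay_s) - exp(-tp / tau_rise_s)
  out <- numeric(length(t))
  pos <- which(t >= 0)
  tt <- t[pos]
  out[pos] <- pmax((exp(-tt / tau_decay_s) - exp(-tt / tau_rise_s)) / peak, 0)
  out
}

#' Time from transient onset to kernel peak
#' @inheritParams calcium_kernel
#' @return Seconds.
#' @export
kernel_time_to_peak <- function(tau_rise_s = 0.1, tau_decay_s = 0.6) {
  stopifnot(tau_rise_s > 0, tau_decay_s > tau_rise_s)
  tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
}

#' Build a table of simulated neuron specifications
#'
#' One row per neuron. `tuning` is `"contra"`, `"ipsi"` or `"untuned"`;
#' tuned neurons respond with `response_amplitude` on preferred-condition
#' trials and `anti_fraction * response_amplitude` on anti-preferred trials;
#' untuned neurons respond with the full amplitude in both conditions (so an
#' untuned neuron with positive amplitude is movement-related but not
#' selective, and one with amplitude 0 is pure noise).
#'
#' @param tuning character vector of tuning labels (recycled against the
#'   longest argument).
#' @param response_amplitude transient amplitude, dF/F units (>= 0).
#' @param anti_fraction fraction of the amplitude expressed on anti-preferred
#'   trials for tuned neurons.
#' @param premotor_lead_s time from transient onset to movement onset; the
#'   default places the kernel peak exactly at movement onset.
#' @param tau_rise_s,tau_decay_s kernel time constants, seconds.
#' @param noise_sd per-frame Gaussian noise s.d., dF/F units.
#' @param baseline_f baseline raw fluorescence (> 0, arbitrary units).
#' @return Tibble with one row per neuron (`neuron_id`, `tuning`,
#'   `response_amplitude`, `anti_fraction`, `premotor_lead_s`, `tau_rise_s`,
#'   `tau_decay_s`, `noise_sd`, `baseline_f`).
#' @export
neuron_spec <- function(tuning = "untuned", response_amplitude = 0.5,
                        anti_fraction = 0.25, premotor_lead_s = NULL,
                        tau_rise_s = 0.1, tau_decay_s = 0.6,
                        noise_sd = 0.05, baseline_f = 100) {
  stopifnot(all(tuning %in% c("contra", "ipsi", "untuned")))
  if (any(response_amplitude < 0))
    stop_config("response_amplitude must be >= 0")
  if (any(tau_rise_s <= 0) || any(tau_decay_s <= tau_rise_s))
    stop_config("taus must satisfy 0 < rise < decay")
  if (any(baseline_f <= 0)) stop_config("baseline_f must be > 0")
  if (is.null(premotor_lead_s))
    premotor_lead_s <- kernel_time_to_peak(tau_rise_s, tau_decay_s)
  n <- max(lengths(list(tuning, response_amplitude, anti_fraction,
                        premotor_lead_s, tau_rise_s, tau_decay_s, noise_sd,
                        baseline_f)))
  tibble::tibble(
    neuron_id = seq_len(n),
    tuning = rep_len(tuning, n),
    response_amplitude = rep_len(response_amplitude, n),
    anti_fraction = rep_len(anti_fraction, n),
    premotor_lead_s = rep_len(premotor_lead_s, n),
    tau_rise_s = rep_len(tau_rise_s, n),
    tau_decay_s = rep_len(tau_decay_s, n),
    noise_sd = rep_len(noise_sd, n),
    baseline_f = rep_len(baseline_f, n))
}

#' Draw a mixed population of neuron specifications
#'
#' Emulates the composition reported for the area under study: a fraction of
#' imaged neurons carries movement-related activity, and within that fraction
#' a minority is significantly selective for the contraversive direction and
#' a smaller minority for the ipsiversive one; the rest of the
#' movement-related neurons respond equally in both conditions, and
#' non-movement neurons are noise-only.
#'
#' @param n number of neurons.
#' @param frac_movement fraction of neurons with movement-related responses.
#' @param frac_contra,frac_ipsi fractions *of the movement-related subset*
#'   tuned to the contraversive / ipsiversive condition.
#' @param response_amplitude,noise_sd,... passed to [neuron_spec()]; the
#'   defaults give an amplitude-to-noise ratio of 3.
#' @param seed integer seed for the composition draw.
#' @return A [neuron_spec()] tibble with a `movement` logical column
#'   recording the ground-truth movement-related label.
#' @export
neuron_population <- function(n, frac_movement = 0.47,
                              frac_contra = 0.245, frac_ipsi = 0.075,
                              response_amplitude = 0.5,
                              noise_sd = response_amplitude / 3,
                              seed = 1L, ...) {
  stopifnot(is_prob(frac_movement), is_prob(frac_contra), is_prob(frac_ipsi),
            frac_contra + frac_ipsi <= 1)
  with_seed(substream_seed(seed, "population"), {
    # the composition fractions are study conditions, so they are realized
    # as exact counts; only the neuron identities are randomized
    n_move <- round(frac_movement * n)
    movement <- sample(rep(c(TRUE, FALSE), c(n_move, n - n_move)))
    n_contra <- round(frac_contra * n_move)
    n_ipsi <- round(frac_ipsi * n_move)
    tuning <- rep("untuned", n)
    move_idx <- which(movement)
    move_idx <- move_idx[sample.int(length(move_idx))]
    tuning[move_idx[seq_len(n_contra + n_ipsi)]] <-
      rep(c("contra", "ipsi"), c(n_contra, n_ipsi))
    amp <- ifelse(movement, response_amplitude, 0)
    specs <- neuron_spec(tuning = tuning, response_amplitude = amp,
                         noise_sd = noise_sd, ...)
    specs$movement <- movement
    specs
  })
}

#' Re-draw tuning labels to emulate suppression-induced plasticity
#'
#' Models the before-to-after change seen after days of contralateral
#' suppression as stochastic tuning transitions: contraversive-tuned neurons
#' lose their preference (become untuned but still movement-responsive) with
#' probability `p_contra_to_none`, and movement-responsive untuned neurons
#' acquire an ipsiversive preference with probability `p_none_to_ipsi`.
#' Amplitudes, kernels and noise are untouched, so the before/after pair is
#' matched neuron by neuron.
#'
#' @param specs a [neuron_spec()] tibble (the "before" population).
#' @param p_contra_to_none,p_none_to_ipsi transition probabilities; the
#'   defaults approximate the reported drop in contraversive-selective and
#'   rise in ipsiversive-selective counts.
#' @param seed integer seed for the transition draw.
#' @return The "after" specification tibble.
#' @export
apply_plasticity <- function(specs, p_contra_to_none = 0.5,
                             p_none_to_ipsi = 0.15, seed = 1L) {
  stopifnot(is_prob(p_contra_to_none), is_prob(p_none_to_ipsi))
  with_seed(substream_seed(seed, "plasticity"), {
    after <- specs
    u <- runif(nrow(specs))
    lose <- specs$tuning == "contra" & u < p_contra_to_none
    gain <- specs$tuning == "untuned" & specs$response_amplitude > 0 &
      u < p_none_to_ipsi
    after$tuning[lose] <- "untuned"
    after$tuning[gain] <- "ipsi"
    after
  })
}

#' Simulate per-neuron raw fluorescence traces for a trial schedule
#'
#' For each neuron, `F(t) = baseline_f * (1 + sum_trials a_eff * K(t - t0) +
#' noise)`, where `K` is the peak-normalized double-exponential kernel,
#' `t0 = movement onset - premotor_lead_s` (so the default peak coincides
#' with movement onset), and `a_eff` is the effective amplitude given the
#' neuron's tuning and the trial's condition. Timeout trials contribute no
#' transient.
#'
#' @param schedule tibble with `target_side` and `true_onset_s` (ground-truth
#'   movement onsets; `NA` for timeouts).
#' @param specs a [neuron_spec()] tibble.
#' @param frame_rate imaging frame rate, Hz.
#' @param hemisphere hemisphere under study, for condition mapping.
#' @param duration_s trace duration; defaults to span the schedule plus 2 s.
#' @param seed integer seed for the noise stream.
#' @return List of class `fluor_data`: `frame_times_s` (length K),
#'   `f` (K x n_neurons matrix of raw fluorescence), `specs`.
#' @export
simulate_calcium <- function(schedule, specs, frame_rate = 6,
                             hemisphere = c("right", "left"),
                             duration_s = NULL, seed = 1L) {
  hemisphere <- match.arg(hemisphere)
  if (nrow(specs) == 0) stop_config("specs must be non-empty")
  if (!"true_onset_s" %in% names(schedule))
    stop_config("schedule lacks ground-truth movement onsets")
  if (is.null(duration_s)) {
    duration_s <- max(schedule$trial_end_s %||% schedule$true_onset_s,
                      na.rm = TRUE) + 2
  }
  frame_dt <- 1 / frame_rate
  if (frame_dt > 0.6)
    stop_config("frame period %.2f s cannot resolve the trial epochs",
                frame_dt)
  frame_times <- seq(0, duration_s, by = frame_dt)
  done <- schedule[!is.na(schedule$true_onset_s), ]
  cond <- movement_condition(done$target_side, hemisphere)
  with_seed(substream_seed(seed, "neural_noise"), {
    n_frames <- length(frame_times)
    f <- matrix(0, n_frames, nrow(specs))
    for (j in seq_len(nrow(specs))) {
      s <- specs[j, ]
      signal <- numeric(n_frames)
      if (s$response_amplitude > 0 && nrow(done) > 0) {
        a_eff <- switch(s$tuning,
          contra = ifelse(cond == "contraversive", s$response_amplitude,
                          s$anti_fraction * s$response_amplitude),
          ipsi = ifelse(cond == "ipsiversive", s$response_amplitude,
                        s$anti_fraction * s$response_amplitude),
          untuned = rep(s$response_amplitude, nrow(done)))
        cutoff <- 10 * s$tau_decay_s  # transient is numerically 0 beyond
        for (k in seq_len(nrow(done))) {
          t0 <- done$true_onset_s[k] - s$premotor_lead_s
          idx <- which(frame_times >= t0 & frame_times <= t0 + cutoff)
          if (length(idx) == 0) next
          signal[idx] <- signal[idx] + a_eff[k] *
            calcium_kernel(frame_times[idx] - t0, s$tau_rise_s, s$tau_decay_s)
        }
      }
      noise <- if (s$noise_sd > 0) rnorm(n_frames, 0, s$noise_sd) else 0
      f[, j] <- s$baseline_f * (1 + signal + noise)
    }
    structure(list(frame_times_s = frame_times, f = f, specs = specs,
                   frame_rate = frame_rate, hemisphere = hemisphere),
              class = "fluor_data")
  })
}

#' @export
print.fluor_data <- function(x, ...) {
  cat(sprintf("<fluor_data> %d neurons x %d frames at %g Hz\n",
              ncol(x$f), nrow(x$f), x$frame_rate))
  invisible(x)
}
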