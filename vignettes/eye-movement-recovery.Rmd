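---
title: "Models and methods: saccade scoring, movement-related activity, and recovery statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: saccade scoring, movement-related activity, and recovery statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaccade)
```

## The experimental design this package analyses

A head-fixed mouse fixates a central LED with its left eye (within a ±2.5°
window, held 750–1000 ms), then shifts its gaze toward a nasal or temporal
target LED within a 10 s response window. A qualifying response is a rapid
eye movement with amplitude > 5° and speed > 0.1°/ms toward the target.
On interleaved trials, one hemisphere's secondary motor cortex (MOs) is
optogenetically suppressed for 1 s after target onset. The analysis
questions are behavioral — how suppression changes the distribution of
reaction times across days — and neural — how the direction preference of
individual MOs neurons in the *unsuppressed* hemisphere, measured by
two-photon calcium imaging before and after days of contralateral
suppression, shifts toward the ipsiversive direction.

The raw recordings behind the original study are not redistributed, so the
package ships a synthetic-session generator that emulates the statistical
structure the analysis assumes, with full ground truth. Every analysis
function is written against the generic data contracts (eye traces, trial
schedules, fluorescence matrices), so real recordings in the documented CSV
/ TIFF / JSON formats can be substituted for the generator's output.

## Saccade detection and trial scoring

Eye position is an azimuthal angle sampled at 500 Hz, positive = temporal
for the tracked left eye. Speed is computed on position smoothed with a
centered 5-sample (10 ms) moving average, differentiated by central
differences (one-sided at the endpoints). Candidate saccades are maximal
runs with |speed| > 0.1°/ms; runs separated by less than 20 ms are merged so
a mid-flight speed dip does not split one saccade in two; amplitude is the
net start-to-end displacement of the run (not path length), and events are
kept when |amplitude| > 5°. Both thresholds are strict inequalities. The
onset/offset criteria, the smoothing window and the merge gap are not fixed
by the task definition; the values above are this package's declared
conventions, all exposed as arguments.

Trial outcomes follow the task rules: the **first** rapid movement after
target onset decides the trial — `correct` if it points at the target with
amplitude > 5° (reaction time = onset − target onset), `wrong_direction` or
`small_amplitude` otherwise; with no rapid movement, a trial is `drift_out`
if the unsmoothed position leaves the ±2.5° window (window violations are
defined on gaze position, not velocity) and `timeout` after 10 s. Timeout
trials are excluded from reaction-time statistics but retained in
denominators of threshold proportions.

## Movement-related activity and selectivity

Raw fluorescence is the pixel sum over each ROI. Within each trial,
ΔF/F = (F − F~baseline~)/F~baseline~ with F~baseline~ the 30th percentile of
the within-trial raw series (linear interpolation between order statistics;
the percentile is taken over the whole trial including pre-fixation frames).
Movement-related activity is

R = ΔF/F(frame at movement onset) − ΔF/F(frame 600 ms earlier),

with frames chosen by nearest timestamp and midpoint ties broken toward the
earlier frame (the frame-selection rule is config-exposed since "the frame
at" leaves rounding open at ~6 Hz).

Per neuron, the per-trial R values in each condition
(contraversive/ipsiversive, mapped from target side and the hemisphere under
study) are tested against zero with a two-sided Wilcoxon signed-rank test;
a neuron is **movement-related** when either condition is significant at
p < 0.05 (strict). Among movement-related neurons, **direction selectivity**
is a two-sided Mann–Whitney test between conditions; the label (contra/ipsi)
follows the larger condition mean. The per-condition R entering the
selectivity index and the difference in ΔF/F increase is the across-trial
mean (config-switchable to median). Both rank tests use exact null
distributions for small tie-free samples (up to 25 non-zero differences /
combined n of 20) and tie-corrected normal approximations otherwise; zero
differences are dropped. Because both tests are two-sided while the
"increase in activity" wording suggests direction, the sign of each
condition mean is reported next to the flags so an increase-only reading can
be audited. No multiple-testing correction is applied across neurons — the
classification is deliberately per-neuron at α = 0.05, which implies a
known ≈9.75% false-positive rate on the movement-related flag (two tests
combined with OR); population percentages reported by `run_study()` include
that rate.

The selectivity index is SI = (R~contra~ − R~ipsi~)/|R~contra~ + R~ipsi~|,
which can exceed ±1 when a condition mean is negative. For before/after
pairs the two sessions share the **larger** of the two denominators,
guarding ΔSI = SI~after~ − SI~before~ against a small denominator produced
by non-significant responses in one session; a zero shared denominator
excludes the neuron. Positive SI means contraversive preference, so
plasticity toward the ipsiversive direction appears as median ΔSI < 0.

## Behavioral statistics

Reaction times are summarised as median ± m.a.d. The sources reporting this
convention do not say whether m.a.d. is the median or the mean absolute
deviation; the package computes the (unscaled) **median** absolute deviation
as primary and offers the mean form behind a flag. Threshold proportions
(RT < 1 s, RT < 10 s) use all trials in the denominator and completed trials
in the numerator. Condition contrasts use the Pearson chi-square statistic
on the 2×2 table of below/at-or-above counts **without** Yates continuity
correction: the uncorrected statistic is the one consistent with the
reported significance bounds when the tables are rebuilt from printed
percentages (the corrected statistic violates one of them), and
`reconstruct_counts()` performs exactly that rebuild (round half away from
zero, with a warning when the count does not round back to the printed
value). Reaction-time distributions are compared with the two-sided
Mann–Whitney test.

## What the generator emulates, and what it does not

`simulate_behavior()` realizes the task state machine on the 500 Hz grid:
settled fixation, a uniform 750–1000 ms hold, target onset, and a
minimum-jerk response saccade at a sampled latency, followed by a
sub-threshold drift back to fixation. Design choices:

* **Latency model.** Per (regime × suppression) cell: a lognormal for
  completed trials plus an explicit timeout probability. Parameters are
  solved analytically so the configured P(RT < 1 s), P(RT < 10 s) and the
  completed-trial median match the regime emulated — first-day suppression
  leaves ~7% of trials below 1 s; the recovered regime is condition-matched
  (suppressed and unsuppressed share one distribution, ~46% below 1 s);
  bilateral suppression reinstates the impairment (~19% vs ~67%). A
  two-parameter lognormal cannot simultaneously match every printed m.a.d.,
  and the quantile constraints win; the generator's m.a.d. values are
  therefore only approximate.
* **Saccade waveform.** Minimum-jerk profile, amplitude uniform on 6–9° and
  duration uniform on 20–30 ms, giving peak speeds ≥ 0.2°/ms. The margins
  (amplitude ≥ 6°, speed ≥ 0.2°/ms against thresholds 5° and 0.1°/ms) let
  tests assert detector recall = precision = 1; the 30 ms duration cap keeps
  the speed-threshold crossing within 6 ms of the true onset under the
  10 ms smoothing window.
* **Noise.** Additive Gaussian position noise (s.d. 0.1°, typical of video
  tracker output) plus a slow ±0.3° sinusoidal drift. Blink artifacts,
  pupil-size coupling and binocular geometry are not modeled, so perfect
  detector scores on synthetic sessions bound real-data performance from
  above rather than certifying it.
* **Calcium.** Per neuron, F(t) = baseline × (1 + Σ amplitude~eff~ ·
  K(t − t₀) + noise), with K a peak-normalized double-exponential kernel
  (rise 0.1 s, decay 0.6 s, GCaMP6m-like) whose peak sits at movement onset
  by default (premotor transient). Tuned neurons express the full amplitude
  on preferred trials and a 0.25 fraction on anti-preferred trials; untuned
  movement-responsive neurons respond equally in both conditions; defaults
  use amplitude 0.5 ΔF/F and noise s.d. amplitude/3 (SNR 3). Photon shot
  noise, neuropil contamination and spike inference are out of scope.
* **Population composition.** Fractions (47% movement-responsive; 24.5% /
  7.5% of those contra/ipsi-tuned) are study conditions, so the generator
  realizes them as exact counts and randomizes only the identities.
* **Plasticity.** The before→after change is modeled as tuning transitions:
  contra→untuned with probability 0.5 and untuned→ipsi with probability
  0.15, approximating the reported drop in contraversive-selective and rise
  in ipsiversive-selective counts; amplitudes and noise stay matched per
  neuron. Optogenetic photophysics is never simulated — suppression exists
  only as a regime flag switching the latency model and, across days, the
  tuning transitions. Laser and LED power settings are carried as metadata
  only.
* **Movies.** `render_movie()` paints ROI intensities over a static textured
  background and applies integer per-frame translations; registration
  (`register_frames()`) exhaustively searches integer shifts maximizing the
  Pearson correlation of the overlap, with the first frame as reference. No
  sub-pixel or line-by-line correction is provided.
* **Randomness.** One RNG substream per concern (behavior, neural noise,
  population, plasticity, movie jitter), each derived from the master seed
  by a stable name hash, so changing one simulation facet leaves the others
  bit-identical. Inter-trial timing (0.5 s settle, 0.5 s post-movement hold,
  1 s return drift) is exposed as configuration; the task definition does
  not fix it.

## Numerical conventions and degenerate inputs

Percentiles use linear interpolation (R type 7). A non-positive ΔF/F
baseline is an error (invalid raw units). Trials whose 600 ms baseline frame
precedes the trial start are excluded and counted. Signed-rank inputs that
are all zero give p = 1 by convention; zero shared denominators exclude a
neuron from SI analyses. Chi-square tables with a zero marginal are errors.
Neurons with fewer than 5 trials in either condition are excluded from
classification with `usable = FALSE`.

## Problem sizes and verification

The packaged study sizes (three behavioral phases of 320/370/145 trials
with suppression probabilities 0.3/0.5/0.3, two imaging sessions of 75
trials, 415 neurons) mirror the session scale of the design the generator
emulates and run end to end in well under a minute. The test suite checks,
among others: exact rank-test p-values against exhaustive enumeration
(n ≤ 8); the Type-I error of the selectivity test on 1000 noise-only
neurons (fraction significant within the 99% binomial band around 0.05);
recovery of a 25%/7% contra/ipsi composition at SNR 3 to within 5
percentage points; a negative-median ΔSI with signed-rank p < 0.01 under
the plasticity regime at n = 200 and its absence under the control regime;
and the full suppressed/recovered/bilateral chi-square pattern on an
end-to-end study run. These checks certify the pipeline on data whose
generating process matches its assumptions; they cannot certify behavior on
artifacts the generator does not model (blinks, z-drift, neuropil).

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_trials = 60, regime = "first_day", seed = 1)
session <- simulate_behavior(cfg)
trials <- score_trials(session$eye_trace, session$schedule)
behavior_summary(trials)
suppression_contrast(trials)

report <- run_study(study_config(seed = 1))
report
write_study_report(report, "study_out")
```
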