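#' Per-condition trial responses for one neuron and session
#'
#' @param r_contra,r_ipsi per-trial movement-related activity values (dF/F
#'   increase) in the contraversive / ipsiversive condition.
#' @param neuron_id,session_tag identifiers (`session_tag` is `"before"` or
#'   `"after"` in paired designs).
#' @return Object of class `neuron_response`.
#' @export
neuron_response <- function(r_contra, r_ipsi, neuron_id = NA_integer_,
                            session_tag = "before") {
  if (anyNA(r_contra) || anyNA(r_ipsi) ||
      any(!is.finite(c(r_contra, r_ipsi))))
    stop_config("trial responses must be finite")
  structure(list(r_contra = as.numeric(r_contra),
                 r_ipsi = as.numeric(r_ipsi),
                 neuron_id = neuron_id, session_tag = session_tag),
            class = "neuron_response")
}

#' Classify a neuron as movement-related and direction-selective
#'
#' A neuron carries significant movement-related activity when the per-trial
#' dF/F increase differs from zero (Wilcoxon signed-rank, strict `p < alpha`)
#' in either the contraversive or the ipsiversive condition. Among
#' movement-related neurons, direction selectivity is decided by a
#' Mann-Whitney test between the two conditions: `"contra"` when significant
#' with a larger contraversive mean, `"ipsi"` for the reverse, `"none"`
#' otherwise. The direction p-value is reported for every neuron — including
#' non-movement-related ones — so the selectivity test can be audited
#' unconditionally, but the `direction` label honours the nested rule
#' (direction other than `"none"` implies `movement_related`). The sign of
#' each condition's mean is reported alongside the flags so an
#' increase-only reading of "movement activity" can be audited as well.
#'
#' @param resp a [neuron_response()].
#' @param alpha significance level (strict inequality).
#' @param min_trials minimum trials required per condition; below it the
#'   neuron is not classifiable.
#' @return Tibble row: `neuron_id`, `movement_related`, `p_contra`,
#'   `p_ipsi`, `direction`, `p_direction`, `mean_contra`, `mean_ipsi`,
#'   `usable` (FALSE when the trial minimum is not met, with all tests NA).
#' @export
classify_neuron <- function(resp, alpha = 0.05, min_trials = 5L) {
  stopifnot(inherits(resp, "neuron_response"))
  if (length(resp$r_contra) < min_trials ||
      length(resp$r_ipsi) < min_trials) {
    return(tibble::tibble(
      neuron_id = resp$neuron_id, movement_related = NA,
      p_contra = NA_real_, p_ipsi = NA_real_, direction = NA_character_,
      p_direction = NA_real_, mean_contra = NA_real_, mean_ipsi = NA_real_,
      usable = FALSE))
  }
  p_c <- wilcoxon_signed_rank(resp$r_contra)$p
  p_i <- wilcoxon_signed_rank(resp$r_ipsi)$p
  movement <- (p_c < alpha) || (p_i < alpha)
  p_dir <- mann_whitney(resp$r_contra, resp$r_ipsi)$p
  m_c <- mean(resp$r_contra)
  m_i <- mean(resp$r_ipsi)
  direction <- "none"
  if (movement && p_dir < alpha) {
    direction <- if (m_c > m_i) "contra" else "ipsi"
  }
  tibble::tibble(
    neuron_id = resp$neuron_id, movement_related = movement,
    p_contra = p_c, p_ipsi = p_i, direction = direction,
    p_direction = p_dir, mean_contra = m_c, mean_ipsi = m_i, usable = TRUE)
}

#' Difference in dF/F increase between conditions
#'
#' The across-trial mean contraversive response minus the mean ipsiversive
#' response; positive values mark a contraversive preference.
#'
#' @param resp a [neuron_response()].
#' @param estimator `"mean"` (conventional) or `"median"`.
#' @return Numeric scalar.
#' @export
diff_dff_increase <- function(resp, estimator = c("mean", "median")) {
  stopifnot(inherits(resp, "neuron_response"))
  estimator <- match.arg(estimator)
  if (length(resp$r_contra) == 0 || length(resp$r_ipsi) == 0)
    stop_config("empty condition")
  est <- if (estimator == "mean") mean else median
  est(resp$r_contra) - est(resp$r_ipsi)
}

#' Selectivity index for contraversive/ipsiversive responses
#'
#' `SI = (R_contra - R_ipsi) / |R_contra + R_ipsi|`. The index can exceed 1
#' or fall below -1 when either condition response is negative. An explicit
#' denominator override supports the shared-denominator before/after pairing
#' of [paired_selectivity()].
#'
#' @param r_contra_mean,r_ipsi_mean condition responses (across-trial means).
#' @param denominator_override optional positive denominator replacing
#'   `|R_contra + R_ipsi|`.
#' @return SI, or `NA_real_` when the effective denominator is zero (the
#'   neuron is excluded from SI analyses).
#' @export
selectivity_index <- function(r_contra_mean, r_ipsi_mean,
                              denominator_override = NULL) {
  d <- denominator_override %||% abs(r_contra_mean + r_ipsi_mean)
  if (d == 0) return(NA_real_)
  (r_contra_mean - r_ipsi_mean) / d
}

#' Paired before/after selectivity with a common larger denominator
#'
#' Both sessions' indices are computed with the larger of the two sessions'
#' `|R_contra + R_ipsi|` values, which guards the index against a small
#' denominator arising from non-significant responses in one session.
#' Classification flags are computed per session and combined with OR, so a
#' neuron counts as movement-related (or direction-selective) when it is so
#' in either session.
#'
#' @param before,after [neuron_response()] objects for the same neuron.
#' @param alpha,min_trials passed to [classify_neuron()].
#' @param estimator condition-response estimator, see [diff_dff_increase()].
#' @return One-row tibble: per-session means, `shared_denominator`,
#'   `si_before`, `si_after`, `delta_si`, per-session and combined
#'   classification flags. SI columns are `NA` (excluded) when the shared
#'   denominator is zero.
#' @export
paired_selectivity <- function(before, after, alpha = 0.05, min_trials = 5L,
                               estimator = c("mean", "median")) {
  stopifnot(inherits(before, "neuron_response"),
            inherits(after, "neuron_response"))
  estimator <- match.arg(estimator)
  est <- if (estimator == "mean") mean else median
  cb <- classify_neuron(before, alpha, min_trials)
  ca <- classify_neuron(after, alpha, min_trials)
  rc_b <- est(before$r_contra)
  ri_b <- est(before$r_ipsi)
  rc_a <- est(after$r_contra)
  ri_a <- est(after$r_ipsi)
  d <- max(abs(rc_b + ri_b), abs(rc_a + ri_a))
  si_b <- selectivity_index(rc_b, ri_b, denominator_override = d)
  si_a <- selectivity_index(rc_a, ri_a, denominator_override = d)
  tibble::tibble(
    neuron_id = before$neuron_id,
    rc_before = rc_b, ri_before = ri_b, rc_after = rc_a, ri_after = ri_a,
    shared_denominator = d,
    si_before = si_b, si_after = si_a,
    delta_si = si_a - si_b,
    movement_before = cb$movement_related, movement_after = ca$movement_related,
    movement_either = isTRUE(cb$movement_related) | isTRUE(ca$movement_related),
    direction_before = cb$direction, direction_after = ca$direction,
    selective_before = isTRUE(cb$usable) & cb$p_direction < alpha,
    selective_after = isTRUE(ca$usable) & ca$p_direction < alpha,
    selective_either = (isTRUE(cb$usable) & cb$p_direction < alpha) |
      (isTRUE(ca$usable) & ca$p_direction < alpha),
    usable = cb$usable & ca$usable)
}

#' Skew of a population distribution away from zero
#'
#' Wilcoxon signed-rank test of the values against zero, with the sample
#' median; used for the population-level bias of the difference in dF/F
#' increase and of the change in selectivity index.
#'
#' @param values numeric vector (non-empty).
#' @return List with `p`, `median` and `n`.
#' @export
population_skew_test <- function(values) {
  res <- wilcoxon_signed_rank(values)
  list(p = res$p, median = median(values), n = length(values))
}

#' Classify every neuron in a per-trial activity table
#'
#' Convenience wrapper: splits a long table of per-trial responses (as
#' produced by [trial_activity()]) by neuron, builds [neuron_response()]
#' objects and classifies each one.
#'
#' @param activity tibble with `neuron_id`, `condition` (`"contraversive"` /
#'   `"ipsiversive"`) and `R`.
#' @param alpha,min_trials passed to [classify_neuron()].
#' @return Tibble with one row per neuron (see [classify_neuron()]) plus
#'   `diff_dff` (difference in dF/F increase) and `si` (single-session
#'   selectivity index).
#' @export
classify_population <- function(activity, alpha = 0.05, min_trials = 5L) {
  split_ids <- split(seq_len(nrow(activity)), activity$neuron_id)
  rows <- lapply(split_ids, function(ii) {
    sub <- activity[ii, ]
    resp <- neuron_response(sub$R[sub$condition == "contraversive"],
                            sub$R[sub$condition == "ipsiversive"],
                            neuron_id = sub$neuron_id[1])
    cl <- classify_neuron(resp, alpha, min_trials)
    cl$diff_dff <- if (cl$usable) diff_dff_increase(resp) else NA_real_
    cl$si <- if (cl$usable) {
      selectivity_index(mean(resp$r_contra), mean(resp$r_ipsi))
    } else NA_real_
    cl
  })
  dplyr::bind_rows(rows)
}
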