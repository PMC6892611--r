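#' Median and median absolute deviation
#'
#' Reaction-time distributions are heavily right-skewed, so they are
#' summarised as median ± m.a.d. The m.a.d. is the unscaled median absolute
#' deviation `median(|x - median(x)|)` by default; the mean absolute
#' deviation is available behind the `form` flag.
#'
#' @param x numeric vector (non-empty).
#' @param form `"median"` (default) or `"mean"` absolute deviation.
#' @return Named numeric vector `c(median, mad)`.
#' @export
median_mad <- function(x, form = c("median", "mean")) {
  form <- match.arg(form)
  if (length(x) == 0) stop_config("empty sample")
  if (anyNA(x)) stop_config("NA in sample")
  m <- median(x)
  dev <- abs(x - m)
  c(median = m, mad = if (form == "median") median(dev) else mean(dev))
}

#' Proportion of trials with a reaction time below a threshold
#'
#' The denominator is *all* trials including timeouts; the numerator counts
#' completed trials with `RT < threshold` (strict). This reconciles
#' proportions quoted over all trials with reaction-time statistics computed
#' over completed trials only.
#'
#' @param reaction_times_s completed-trial reaction times, seconds.
#' @param n_total total number of trials including timeouts (must be at
#'   least the number of completed trials).
#' @param threshold_s threshold in seconds.
#' @return Proportion in `[0, 1]`.
#' @export
proportion_below <- function(reaction_times_s, n_total, threshold_s) {
  if (!is_number(n_total) || n_total < 1) stop_config("n_total must be >= 1")
  if (length(reaction_times_s) > n_total)
    stop_config("more reaction times than trials")
  if (anyNA(reaction_times_s)) stop_config("NA reaction times")
  sum(reaction_times_s < threshold_s) / n_total
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uses the closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with no
#' continuity correction, and the chi-square distribution with one degree of
#' freedom.
#'
#' @param a,b,c,d non-negative integer counts: rows are conditions, columns
#'   below / at-or-above the threshold.
#' @return List with `statistic` and `p`.
#' @export
pearson_chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_config("counts must be non-negative integers")
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop_config("zero marginal in contingency table")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Rebuild an integer count from a printed percentage
#'
#' Inverts reporting of the form "x% of n trials": `round(percent/100 * n)`
#' with half-away-from-zero rounding. Warns when the recovered count does not
#' round back to the printed percentage at one-decimal precision.
#'
#' @param percent printed percentage in `[0, 100]`.
#' @param n denominator (>= 1).
#' @return Integer count.
#' @export
reconstruct_counts <- function(percent, n) {
  stopifnot(is_number(percent), percent >= 0, percent <= 100,
            is_number(n), n >= 1)
  count <- floor(percent / 100 * n + 0.5)
  if (abs(round(count / n * 100, 1) - percent) > 0.05)
    warning(sprintf("count %d/%d gives %.1f%%, printed value was %.1f%%",
                    count, n, count / n * 100, percent))
  as.integer(count)
}

#' Compare two reaction-time distributions
#'
#' Two-sided Mann-Whitney U test on completed-trial reaction times, with
#' median ± m.a.d. per sample.
#'
#' @param x,y completed-trial reaction times, seconds (both non-empty).
#' @return List with `p`, `summary_x`, `summary_y` (each `c(median, mad)`).
#' @export
compare_rt_distributions <- function(x, y) {
  res <- mann_whitney(x, y)
  list(p = res$p, summary_x = median_mad(x), summary_y = median_mad(y))
}

#' Behavioral summary per suppression condition
#'
#' @param trials scored trial table from [score_trials()].
#' @param thresholds_s reaction-time thresholds for the proportion columns.
#' @return Tibble, one row per suppression condition: `n_total`,
#'   `n_completed`, `median_rt_s`, `mad_rt_s`, `prop_lt_1s`, `prop_lt_10s`.
#' @export
behavior_summary <- function(trials, thresholds_s = c(1, 10)) {
  groups <- split(seq_len(nrow(trials)), trials$suppressed)
  rows <- lapply(names(groups), function(g) {
    sub <- trials[groups[[g]], ]
    rts <- sub$reaction_time_s[sub$outcome == "correct"]
    mm <- if (length(rts) > 0) median_mad(rts) else c(median = NA, mad = NA)
    row <- tibble::tibble(
      suppressed = as.logical(g), n_total = nrow(sub),
      n_completed = length(rts),
      median_rt_s = unname(mm["median"]), mad_rt_s = unname(mm["mad"]))
    for (th in thresholds_s) {
      row[[sprintf("prop_lt_%gs", th)]] <-
        proportion_below(rts, nrow(sub), th)
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$suppressed), ]
}

#' Suppressed-vs-unsuppressed contrast within a scored session
#'
#' Chi-square on the below-threshold proportion (all trials) and
#' Mann-Whitney on the completed-trial reaction times.
#'
#' @param trials scored trial table with both suppression conditions.
#' @param threshold_s reaction-time threshold for the chi-square contrast.
#' @return List with `chi2`, `p_chi2`, `p_mannwhitney` and the per-condition
#'   summary table.
#' @export
suppression_contrast <- function(trials, threshold_s = 1) {
  s <- trials[trials$suppressed, ]
  u <- trials[!trials$suppressed, ]
  if (nrow(s) == 0 || nrow(u) == 0)
    stop_config("both suppression conditions required")
  below <- function(tt) sum(tt$outcome == "correct" &
                              tt$reaction_time_s < threshold_s)
  bs <- below(s)
  bu <- below(u)
  chi <- pearson_chi2_2x2(bs, nrow(s) - bs, bu, nrow(u) - bu)
  rts_s <- s$reaction_time_s[s$outcome == "correct"]
  rts_u <- u$reaction_time_s[u$outcome == "correct"]
  p_mw <- if (length(rts_s) > 0 && length(rts_u) > 0) {
    mann_whitney(rts_s, rts_u)$p
  } else NA_real_
  list(chi2 = chi$statistic, p_chi2 = chi$p, p_mannwhitney = p_mw,
       summary = behavior_summary(trials))
}
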