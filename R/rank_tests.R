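#' Two-sided Wilcoxon signed-rank test against zero
#'
#' Conventions used throughout the classification: zero differences are
#' dropped before ranking; if nothing remains the p-value is 1; the exact
#' null distribution is used for up to 25 non-zero differences when the
#' absolute values are tie-free, and a tie-corrected normal approximation
#' otherwise.
#'
#' @param diffs numeric vector of paired differences (non-empty).
#' @param exact_max largest tie-free sample size handled exactly.
#' @return List with `p` (two-sided p-value), `statistic` (sum of positive
#'   ranks `W`), `n` (non-zero differences used) and `method`.
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 25L) {
  if (length(diffs) == 0) stop_config("empty input")
  if (anyNA(diffs)) stop_config("NA differences")
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p = 1, statistic = NA_real_, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    # W is integer-valued under the tie-free exact null
    p_le <- psignrank(w, n)
    p_ge <- 1 - psignrank(w - 1, n)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(p = p, statistic = w, n = n, method = method)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution for combined sample sizes up to `exact_max` when
#' there are no ties across the pooled sample; tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_max largest tie-free combined size handled exactly.
#' @return List with `p`, `statistic` (U for the first sample), `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 20L) {
  if (length(x) == 0 || length(y) == 0) stop_config("empty input")
  if (anyNA(x) || anyNA(y)) stop_config("NA values")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && nx + ny <= exact_max) {
    p_le <- pwilcox(u, nx, ny)
    p_ge <- 1 - pwilcox(u - 1, nx, ny)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    nn <- nx + ny
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 *
      ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(p = p, statistic = u, n = c(nx, ny), method = method)
}
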