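## ---------------------------------------------------------------------------
## Nonparametric comparisons and summaries: rank-sum, sign-rank, Bonferroni,
## mean +/- SEM, median +/- MAD, first-vs-last-trial integrity check.
## ---------------------------------------------------------------------------

comparisonRow <- function(test, label, n1, n2, statistic, p) {
  data.frame(test = test, label = label, n1 = n1, n2 = n2,
             statistic = unname(statistic), p_value = unname(p),
             p_adjusted = NA_real_, stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; normal approximation with tie correction (and
#' continuity correction) otherwise.  Mid-ranks handle ties.
#'
#' @param a,b numeric samples (both non-empty).
#' @param label comparison label carried into reports.
#' @return One-row comparison data frame with columns `test`, `label`, `n1`,
#'   `n2`, `statistic` (the Mann-Whitney U of `a`), `p_value`, `p_adjusted`
#'   (`NA` until [adjustBonferroni()]).
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))
#' @export
rankSumTest <- function(a, b, label = "") {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  exact <- (length(a) + length(b) <= 20L) && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  comparisonRow("rank_sum", label, length(a), length(b),
                wt$statistic, wt$p.value)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped before ranking; if every difference is zero
#' the test is undefined and an error is raised.  Exact for at most 15
#' non-zero tie-free differences, normal approximation otherwise.
#'
#' @param a,b paired numeric samples of equal length (`b` may be omitted to
#'   test differences `a` against zero).
#' @param label comparison label.
#' @return One-row comparison data frame (`n1` = `n2` = number of non-zero
#'   differences).
#' @export
signRankTest <- function(a, b = NULL, label = "") {
  d <- if (is.null(b)) a else {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    a - b
  }
  if (length(d) < 1L) stop("empty sample")
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("all paired differences are zero; the signed-rank test is undefined")
  exact <- length(d) <= 15L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  comparisonRow("sign_rank", label, length(d), length(d),
                wt$statistic, wt$p.value)
}

#' Bonferroni correction with an explicit family size
#'
#' `p_adjusted = min(1, p * n_comparisons)`; the family size is the number of
#' pairwise comparisons in the reported panel (e.g. 3 for the three pulse
#' durations), stated explicitly per analysis.
#'
#' @param comparisons a comparison data frame (rows from [rankSumTest()] /
#'   [signRankTest()], possibly `rbind`-ed).
#' @param n_comparisons family size; defaults to the number of rows.
#' @return The data frame with `p_adjusted` filled in.
#' @export
adjustBonferroni <- function(comparisons, n_comparisons = nrow(comparisons)) {
  comparisons$p_adjusted <- pmin(1, comparisons$p_value * n_comparisons)
  comparisons
}

#' Center and spread summaries
#'
#' `mean_sem`: mean with SEM = sd/sqrt(n) (the default presentation);
#' `median_mad`: median with the unscaled median absolute deviation (the
#' presentation used for decay-time distributions).  Spread is `NA` for a
#' single observation.
#'
#' @param x numeric sample (NAs dropped).
#' @param mode `"mean_sem"` or `"median_mad"`.
#' @return Named numeric vector `c(center, spread)`.
#' @examples
#' summarizeSample(c(20, 30, 40), "median_mad")
#' @export
summarizeSample <- function(x, mode = c("mean_sem", "median_mad")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]
  if (length(x) < 1L) stop("empty sample")
  if (mode == "mean_sem") {
    c(center = mean(x),
      spread = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_)
  } else {
    c(center = stats::median(x),
      spread = if (length(x) > 1L) stats::mad(x, constant = 1) else NA_real_)
  }
}

#' Electrode-integrity check: first vs last trials
#'
#' Compares, across sessions, the first-trial and last-trial time courses on
#' two features: the peak response (value at t = 20 ms) and the slow-phase
#' amplitude (mean over a late window, 60-100 ms by default, after the fast
#' decay).  A deteriorating electrode would predict decreasing responses over
#' trials; stationary sessions should show no significant difference
#' (rank-sum across sessions).
#'
#' @param trial_tcs list (one per session, >= 2 sessions) of
#'   `trials x frames` matrices of per-trial ROI time courses, each with
#'   >= 2 trials.
#' @param time_ms shared frame-time axis (ms).
#' @param t_peak_ms peak anchor (ms).
#' @param slow_window_ms length-2 window (ms) defining the slow phase.
#' @return Two-row comparison data frame (labels `"peak"` and
#'   `"slow_phase"`).
#' @export
firstLastTrialCheck <- function(trial_tcs, time_ms, t_peak_ms = 20,
                                slow_window_ms = c(60, 100)) {
  if (!is.list(trial_tcs) || length(trial_tcs) < 2L)
    stop("need >= 2 sessions")
  if (any(vapply(trial_tcs, nrow, integer(1)) < 2L))
    stop("each session needs >= 2 trials")
  pk <- frameAt(time_ms, t_peak_ms)
  slow_cols <- which(time_ms >= slow_window_ms[1] - 1e-9 &
                       time_ms <= slow_window_ms[2] + 1e-9)
  feat <- function(m, cols) {
    first <- m[1, , drop = FALSE]; last <- m[nrow(m), , drop = FALSE]
    c(first = mean(first[, cols]), last = mean(last[, cols]))
  }
  pk_f <- t(vapply(trial_tcs, feat, numeric(2), cols = pk))
  sl_f <- t(vapply(trial_tcs, feat, numeric(2), cols = slow_cols))
  rbind(
    rankSumTest(pk_f[, "first"], pk_f[, "last"], label = "peak"),
    rankSumTest(sl_f[, "first"], sl_f[, "last"], label = "slow_phase")
  )
}
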