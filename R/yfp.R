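## ---------------------------------------------------------------------------
## YFP expression-area quantification: min-max normalization, 2-SD
## thresholded pixel counts, and a label-shuffle group comparison.
## ---------------------------------------------------------------------------

#' Normalize a YFP image to [0, 1]
#'
#' Min-max scaling `(v - min) / (max - min)` within the chamber mask,
#' accounting for differences in imaging conditions across animals.  A
#' percentile-clipped variant (values clipped to the given quantiles before
#' scaling) is available for robustness to hot pixels.
#'
#' @param img a [YFPImage].
#' @param clip optional length-2 probability vector (e.g. `c(0.01, 0.99)`);
#'   `NULL` for plain min-max.
#' @return The normalized [YFPImage] (idempotent for already-normalized
#'   images when `clip` is `NULL`).
#' @export
normalizeYfp <- function(img, clip = NULL) {
  stopifnot(is(img, "YFPImage"))
  v <- img@data[img@mask]
  if (length(unique(v)) < 2L)
    stop("cannot normalize a constant image (max equals min)")
  if (!is.null(clip)) {
    q <- stats::quantile(v, clip, names = FALSE)
    img@data[img@data < q[1]] <- q[1]
    img@data[img@data > q[2]] <- q[2]
    v <- img@data[img@mask]
  }
  rng <- range(v)
  img@data <- (img@data - rng[1]) / (rng[2] - rng[1])
  img@normalized <- TRUE
  img
}

#' Count expressing pixels by the 2-SD rule
#'
#' Number of chamber pixels whose normalized value exceeds the image's own
#' mean + 2 SD (mean and SD over chamber pixels).  Being a z-score rule, the
#' count is invariant to affine rescaling of the image; strict inequality at
#' the threshold keeps ties deterministic.
#'
#' @param img a normalized [YFPImage] (see [normalizeYfp()]).
#' @return Integer pixel count.
#' @export
countExpressingPixels <- function(img) {
  stopifnot(is(img, "YFPImage"))
  if (!img@normalized)
    stop("image must be normalized first (normalizeYfp)")
  v <- img@data[img@mask]
  s <- stats::sd(v)
  if (is.na(s) || s == 0) return(0L)
  sum(v > mean(v) + 2 * s)
}

#' Label-shuffle control for the group difference in expression area
#'
#' Observed statistic: mean per-animal pixel count of the second group minus
#' the first (by default, long minus short expression).  Under each
#' permutation of the group labels the difference is recomputed; all distinct
#' label assignments are enumerated when there are at most `n_perm` of them,
#' otherwise `n_perm` random permutations are drawn under `seed`.  Returns
#' the shuffled mean and SD and the z-like score
#' `(observed - shuffled mean) / shuffled SD`.
#'
#' @param counts numeric per-animal pixel counts.
#' @param groups factor (or character) of group labels, two levels; the
#'   difference is `mean(level 2) - mean(level 1)`.
#' @param n_perm maximum number of permutations.
#' @param seed integer RNG seed for the random-permutation branch.
#' @return A list with `observed`, `shuffled_mean`, `shuffled_sd`, `z`,
#'   `n_perm_used` and `exhaustive`.
#' @examples
#' groupDifferenceShuffle(c(231, 250, 420, 455),
#'                        c("short", "short", "long", "long"),
#'                        n_perm = 100)
#' @export
groupDifferenceShuffle <- function(counts, groups, n_perm = 10000,
                                   seed = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 animals")
  lv <- levels(groups)
  n <- length(counts)
  idx2 <- which(groups == lv[2])
  k <- length(idx2)
  diff_for <- function(sel2) mean(counts[sel2]) - mean(counts[-sel2])
  observed <- diff_for(idx2)
  n_all <- choose(n, k)
  if (n_all <= n_perm) {
    sets <- utils::combn(n, k, simplify = FALSE)
    diffs <- vapply(sets, diff_for, numeric(1))
    exhaustive <- TRUE
  } else {
    diffs <- withSeed(seed, vapply(seq_len(n_perm), function(i)
      diff_for(sample.int(n, k)), numeric(1)))
    exhaustive <- FALSE
  }
  m <- mean(diffs); s <- stats::sd(diffs)
  list(observed = observed, shuffled_mean = m, shuffled_sd = s,
       z = (observed - m) / s, n_perm_used = length(diffs),
       exhaustive = exhaustive)
}
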