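## ---------------------------------------------------------------------------
## Per-pixel decay-time-to-threshold maps and their central/distal
## distributions; bi-exponential decay fitting for parameter recovery.
## ---------------------------------------------------------------------------

#' Per-pixel decay time to threshold
#'
#' For each pixel, the peak reference is its delta-f/f value at the anchor
#' frame `t_start_ms` (t = 20 ms, where the response peaks) and the threshold
#' is `threshold_fraction` of that peak (70% characterizes the early fast
#' decay, 30% the slower decline).  The decay time is the first time
#' t >= t_start at which the descending signal is below the threshold, with
#' sub-frame precision by linear interpolation between the last frame at or
#' above and the first frame below the threshold.  A pixel already below at
#' the anchor gets `t_start_ms`; pixels with non-positive peak, invalid
#' pixels, and pixels never crossing within the window are `NA` (excluded,
#' not right-censored) and the never-crossed count is recorded.  Because the
#' threshold is a fraction of each pixel's own peak, the map is invariant to
#' positive rescaling of the movie.
#'
#' @param movie a [DffMovie].
#' @param threshold_fraction fraction of peak in (0, 1).
#' @param t_start_ms anchor time (ms); the frame there must be valid.
#' @param t_end_ms end of the analysis window (ms); defaults to the last
#'   frame.
#' @return A [DecayMap].
#' @export
decayTimeMap <- function(movie, threshold_fraction, t_start_ms = 20,
                         t_end_ms = NULL) {
  stopifnot(is(movie, "DffMovie"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  t_end_ms <- t_end_ms %||% max(movie@time_ms)
  ks <- which(movie@valid_frames & movie@time_ms >= t_start_ms - 1e-9 &
                movie@time_ms <= t_end_ms + 1e-9)
  if (length(ks) < 1L) stop("empty analysis window")
  k0 <- frameAt(movie@time_ms, t_start_ms)
  if (!movie@valid_frames[k0])
    stop(sprintf("anchor frame at t = %g ms is invalid", t_start_ms))
  tt <- movie@time_ms[ks]
  nr <- dim(movie@data)[2]; nc <- dim(movie@data)[3]
  ## pixels x frames matrix of the windowed signal (column-major pixels)
  V <- matrix(aperm(movie@data[ks, , , drop = FALSE], c(2, 3, 1)),
              nrow = nr * nc, ncol = length(ks))
  peak <- V[, 1]
  ok <- as.vector(movie@valid_pixels) & !is.na(peak) & peak > 0
  times <- rep(NA_real_, nr * nc)
  if (any(ok)) {
    thr <- threshold_fraction * peak
    below <- V < thr                         # elementwise, recycles thr by col
    for (i in which(ok)) {
      b <- below[i, ]
      j <- which(b)[1]
      if (is.na(j)) next                     # never crossed
      if (j == 1L) { times[i] <- tt[1]; next }
      v1 <- V[i, j - 1L]; v2 <- V[i, j]
      times[i] <- tt[j - 1L] +
        (tt[j] - tt[j - 1L]) * (v1 - thr[i]) / (v1 - v2)
    }
  }
  times_m <- matrix(times, nr, nc)
  DecayMap(times_ms = times_m, threshold_fraction = threshold_fraction,
           peak = matrix(peak, nr, nc),
           valid = matrix(!is.na(times), nr, nc),
           t_start_ms = t_start_ms, t_end_ms = t_end_ms,
           n_not_crossed = sum(ok & is.na(times)),
           condition = movie@condition, session_id = movie@session_id)
}

#' Central and distal decay-time distributions
#'
#' Pools the per-pixel decay times of a central band (ring1, 150-350 um from
#' the response peak) and a distal band (ring3, 1250-1450 um) across one or
#' more sessions, and summarizes each band as median +/- MAD (median absolute
#' deviation from the median, unscaled).
#'
#' @param maps a [DecayMap] or list of them (one per session).
#' @param rings a [RingSet] or list of them matching `maps`.
#' @param central_band,distal_band band names (see [ringBands]).
#' @return A list with `central` and `distal` pooled decay-time vectors and
#'   `summary`, a data frame with columns `band`, `n`, `n_missing`, `median`,
#'   `mad`.
#' @export
decayDistributions <- function(maps, rings, central_band = "ring1",
                               distal_band = "ring3") {
  if (is(maps, "DecayMap")) maps <- list(maps)
  if (is(rings, "RingSet")) rings <- list(rings)
  if (length(maps) != length(rings))
    stop("need one ring set per decay map")
  pool <- function(band) {
    out <- list(vals = numeric(0), n_missing = 0L)
    for (i in seq_along(maps)) {
      rset <- rings[[i]]
      sel <- !is.na(rset@label) & rset@label %in% bandRings(rset, band)
      v <- maps[[i]]@times_ms[sel]
      out$vals <- c(out$vals, v[!is.na(v)])
      out$n_missing <- out$n_missing + sum(is.na(v))
    }
    out
  }
  ctr <- pool(central_band); dst <- pool(distal_band)
  if (length(ctr$vals) == 0L || length(dst$vals) == 0L)
    stop("a band contains no defined decay times")
  summ <- function(band, p) data.frame(
    band = band, n = length(p$vals), n_missing = p$n_missing,
    median = stats::median(p$vals),
    mad = stats::mad(p$vals, constant = 1),
    stringsAsFactors = FALSE
  )
  list(central = ctr$vals, distal = dst$vals,
       summary = rbind(summ("central", ctr), summ("distal", dst)))
}

#' Fit a two-component exponential decay
#'
#' Fits `v(t) = v_peak [w exp(-(t - t_peak)/tau_fast) +
#' (1 - w) exp(-(t - t_peak)/tau_slow)]` to a decaying time course from the
#' anchor frame onward, by Levenberg-Marquardt least squares.  Used to verify
#' that the generator's decay time constants are recoverable through the
#' pipeline.
#'
#' @param time_ms,values the time course (only `t >= t_peak_ms` with finite
#'   values is used).
#' @param t_peak_ms anchor time (ms); the value there defines `v_peak`.
#' @param start named list of starting values (`w`, `tau_fast`, `tau_slow`).
#' @return A list with `w_fast`, `tau_fast_ms`, `tau_slow_ms` (ordered so
#'   `tau_fast_ms <= tau_slow_ms`) and the fitted object.
#' @export
fitDecayTaus <- function(time_ms, values, t_peak_ms = 20,
                         start = list(w = 0.5, tau_fast = 10, tau_slow = 80)) {
  keep <- time_ms >= t_peak_ms - 1e-9 & is.finite(values)
  t <- time_ms[keep]; v <- values[keep]
  if (length(t) < 4L) stop("too few points to fit a bi-exponential")
  vp <- v[which.min(abs(t - t_peak_ms))]
  if (vp <= 0) stop("peak value must be > 0")
  df <- data.frame(s = t - t_peak_ms, y = v / vp)
  fit <- minpack.lm::nlsLM(
    y ~ w * exp(-s / tf) + (1 - w) * exp(-s / ts),
    data = df,
    start = list(w = start$w, tf = start$tau_fast, ts = start$tau_slow),
    lower = c(w = 0, tf = 1e-3, ts = 1e-3),
    upper = c(w = 1, tf = 1e4, ts = 1e4),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  w <- cf[["w"]]; tf <- cf[["tf"]]; ts <- cf[["ts"]]
  if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp; w <- 1 - w }
  list(w_fast = w, tau_fast_ms = tf, tau_slow_ms = ts, fit = fit)
}
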