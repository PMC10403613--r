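## ---------------------------------------------------------------------------
## Peak-ROI time courses and the normalization schemes used to compare
## pulse durations, expression times and stimulation modalities.
## ---------------------------------------------------------------------------

#' Locate the peak-response pixel
#'
#' Finds the pixel of maximal delta-f/f on the (boxcar-smoothed) frame at
#' `t_peak_ms`, the anchor frame of all analyses (t = 20 ms, the first
#' artifact-free frame).  Masked pixels are excluded; ties break to the
#' smallest (row, col) in lexicographic order.  The result is invariant to
#' any positive global rescaling of the movie.
#'
#' @param movie a [DffMovie].
#' @param t_peak_ms anchor time (ms); the frame there must be valid.
#' @param smooth_px odd boxcar width in pixels applied before the argmax
#'   (1 = no smoothing).
#' @return Integer (row, col) of the peak pixel.
#' @export
findPeakCenter <- function(movie, t_peak_ms = 20, smooth_px = 3L) {
  stopifnot(is(movie, "DffMovie"))
  k <- frameAt(movie@time_ms, t_peak_ms)
  if (!movie@valid_frames[k])
    stop(sprintf("frame at t = %g ms is invalid", t_peak_ms))
  m <- movie@data[k, , ]
  m[!movie@valid_pixels] <- NA_real_
  sm <- boxcarSmooth(m, as.integer(smooth_px))
  sm[!movie@valid_pixels] <- NA_real_
  if (all(is.na(sm))) stop("all pixels are invalid at the anchor frame")
  mx <- max(sm, na.rm = TRUE)
  cand <- which(sm == mx, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  as.integer(cand[1, ])
}

#' Pixels of a circular ROI
#'
#' Membership rule: pixel-center Euclidean distance to the ROI center
#' `<= radius_px` (a radius-5 ROI holds 81 pixels).
#'
#' @param movie a [DffMovie] (geometry source).
#' @param center_px ROI center (row, col).
#' @param radius_px ROI radius in pixels.
#' @return Logical rows x cols membership matrix.
#' @export
circleROI <- function(movie, center_px, radius_px = 5) {
  acq <- movie@acq
  circleMask(acq@height_px, acq@width_px, center_px, radius_px)
}

#' Extract the ROI time course
#'
#' Per-frame mean of the trial-averaged delta-f/f over the valid pixels of a
#' circular ROI centered at the peak response, with the across-trial SEM of
#' the per-trial ROI means.  Invalid frames carry `NA`.
#'
#' @param movie a [DffMovie].
#' @param center_px ROI center (row, col), e.g. from [findPeakCenter()].
#' @param radius_px ROI radius in pixels (5 by convention).
#' @return A time-course data frame with columns `time_ms`, `value`, `sem`,
#'   `n_trials`, `condition`, `session_id`, `normalization`.
#' @examples
#' p <- vsdPreset("long_exp")
#' ses <- simulateSession(AcquisitionSpec(), p$stim, p$resp, p$art,
#'                        4, 2, seed = 1)
#' mv <- preprocessSession(ses$stimulated, ses$blank)
#' tc <- extractTimeCourse(mv, findPeakCenter(mv))
#' head(tc)
#' @export
extractTimeCourse <- function(movie, center_px, radius_px = 5) {
  stopifnot(is(movie, "DffMovie"))
  roi <- circleROI(movie, center_px, radius_px) & movie@valid_pixels
  if (!any(roi)) stop("ROI contains no valid pixels")
  nf <- dim(movie@data)[1]
  vals <- vapply(seq_len(nf), function(k) {
    if (!movie@valid_frames[k]) return(NA_real_)
    mean(movie@data[k, , ][roi], na.rm = TRUE)
  }, numeric(1))
  tm <- trialMeans(movie, roi)
  sems <- vapply(seq_len(nf), function(k) {
    if (!movie@valid_frames[k]) return(NA_real_)
    semOf(tm[, k])
  }, numeric(1))
  data.frame(
    time_ms = movie@time_ms, value = vals, sem = sems,
    n_trials = movie@n_trials, condition = movie@condition,
    session_id = movie@session_id, normalization = "raw",
    stringsAsFactors = FALSE
  )
}

#' Per-trial ROI mean time courses
#'
#' @param movie a [DffMovie] with retained per-trial data.
#' @param roi logical membership matrix (combined with the movie's valid
#'   pixels).
#' @return Matrix `trials x frames` of per-trial ROI means (`NA` at invalid
#'   frames).
#' @export
trialMeans <- function(movie, roi) {
  roi <- roi & movie@valid_pixels
  n_tr <- movie@n_trials
  nf <- dim(movie@data)[1]
  out <- matrix(NA_real_, n_tr, nf)
  for (tr in seq_len(n_tr)) {
    for (k in seq_len(nf)) {
      if (!movie@valid_frames[k]) next
      out[tr, k] <- mean(movie@trials[tr, k, , ][roi], na.rm = TRUE)
    }
  }
  out
}

#' Value of a time course at a given time
#'
#' @param tc a time-course data frame.
#' @param t_ms time (ms) of the requested frame.
#' @return The `value` entry at that frame.
#' @export
tcValueAt <- function(tc, t_ms) {
  tc$value[frameAt(tc$time_ms, t_ms)]
}

#' Normalize a session's time courses to its 10 ms condition
#'
#' Within one session, divides every condition's time course by the 10 ms
#' condition's value at the first artifact-free frame (t = 20 ms), so the
#' 10 ms condition's own value there becomes exactly 1.  This removes
#' across-session amplitude variance (staining quality, expression level)
#' before grand averaging.
#'
#' @param tcs named list of time-course data frames for one session; one
#'   element must be the reference condition.
#' @param ref_condition name of the reference element (default `"10ms"`).
#' @param t_ref_ms reference time (ms).
#' @return The list with `value` and `sem` rescaled and the normalization tag
#'   set to `"norm_to_10ms"`.
#' @export
normalizeTo10ms <- function(tcs, ref_condition = "10ms", t_ref_ms = 20) {
  if (!ref_condition %in% names(tcs))
    stop(sprintf("reference condition '%s' not present", ref_condition))
  nrm <- tcValueAt(tcs[[ref_condition]], t_ref_ms)
  if (is.na(nrm) || nrm <= 0)
    stop("reference value at the normalization frame must be > 0")
  lapply(tcs, function(tc) {
    tc$value <- tc$value / nrm
    tc$sem <- tc$sem / nrm
    tc$normalization <- "norm_to_10ms"
    tc
  })
}

#' Normalize a time course to its own peak
#'
#' Divides a time course by its own value at the anchor frame (t = 20 ms by
#' convention, where the response peaks) or, optionally, by its global
#' maximum.  Used to compare decay dynamics across conditions irrespective of
#' amplitude.
#'
#' @param tc a time-course data frame.
#' @param t_peak_ms anchor time (ms).
#' @param use_max if `TRUE`, normalize to the global maximum of the valid
#'   frames instead of the anchor-frame value.
#' @return The normalized time course (tag `"norm_to_own_peak"`).
#' @export
normalizeToOwnPeak <- function(tc, t_peak_ms = 20, use_max = FALSE) {
  nrm <- if (use_max) max(tc$value, na.rm = TRUE)
         else tcValueAt(tc, t_peak_ms)
  if (is.na(nrm) || nrm <= 0) stop("peak value must be > 0")
  tc$value <- tc$value / nrm
  tc$sem <- tc$sem / nrm
  tc$normalization <- "norm_to_own_peak"
  tc
}

#' Grand average of per-session time courses
#'
#' Frame-wise mean and SEM across sessions (mask-aware: a session's invalid
#' frame is excluded from that frame's mean).
#'
#' @param tcs list of time-course data frames with identical time axes.
#' @return A data frame with columns `time_ms`, `value`, `sem`, `n`
#'   (sessions contributing per frame), `condition`, `normalization`.
#' @export
grandAverage <- function(tcs) {
  if (length(tcs) < 1L) stop("no sessions supplied")
  tax <- tcs[[1]]$time_ms
  for (tc in tcs)
    if (length(tc$time_ms) != length(tax) || any(abs(tc$time_ms - tax) > 1e-9))
      stop("sessions have mismatched time axes")
  vals <- do.call(rbind, lapply(tcs, `[[`, "value"))
  data.frame(
    time_ms = tax,
    value = apply(vals, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }),
    sem = apply(vals, 2, semOf),
    n = apply(vals, 2, function(v) sum(!is.na(v))),
    condition = tcs[[1]]$condition[1],
    normalization = tcs[[1]]$normalization[1],
    stringsAsFactors = FALSE
  )
}
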