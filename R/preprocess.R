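## ---------------------------------------------------------------------------
## Preprocessing: raw trial stacks -> trial-averaged, artifact-cleaned
## delta-f/f movies (frame-zero division, blank subtraction, masking).
## ---------------------------------------------------------------------------

#' Frame-zero division
#'
#' Converts raw fluorescence to per-trial delta-f/f: each pixel of each trial
#' is divided by that trial's pre-stimulus baseline mean at the same pixel
#' (the mean over frames before `onset_frame`) and 1 is subtracted, so the
#' pre-stimulus signal sits near 0.
#'
#' @param stack a [TrialStack] of raw fluorescence.
#' @return 4-D array `trials x frames x rows x cols` of per-trial delta-f/f.
#' @export
frameZeroDivide <- function(stack) {
  stopifnot(is(stack, "TrialStack"))
  acq <- stack@acq
  b_idx <- seq_len(acq@onset_frame - 1L)
  if (length(b_idx) < 1L) stop("at least one pre-stimulus frame is required")
  d <- stack@data
  n_tr <- dim(d)[1]
  out <- array(NA_real_, dim(d))
  for (tr in seq_len(n_tr)) {
    B <- if (length(b_idx) == 1L) d[tr, b_idx, , ]
         else colMeans(d[tr, b_idx, , , drop = FALSE][1, , , , drop = TRUE])
    bad <- which(B <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf(
        "non-positive baseline fluorescence at pixel (%d, %d) of trial %d",
        bad[1, 1], bad[1, 2], tr))
    for (k in seq_len(dim(d)[2])) out[tr, k, , ] <- d[tr, k, , ] / B - 1
  }
  out
}

#' Blank-trial subtraction
#'
#' Subtracts the frame-wise mean over blank (no-stimulation) trials from each
#' stimulated trial, removing slow shared components (heartbeat, dye
#' bleaching, drift) that frame-zero division leaves behind.
#'
#' @param dff_stim 4-D per-trial delta-f/f array of the stimulated condition.
#' @param dff_blank 4-D per-trial delta-f/f array of the blank condition,
#'   with matching frame and image dimensions.
#' @return Corrected 4-D per-trial delta-f/f array.
#' @export
blankSubtract <- function(dff_stim, dff_blank) {
  if (length(dim(dff_stim)) != 4L || length(dim(dff_blank)) != 4L)
    stop("inputs must be 4-D per-trial delta-f/f arrays")
  if (!all(dim(dff_stim)[-1] == dim(dff_blank)[-1]))
    stop("stimulated and blank stacks have mismatched geometry")
  if (dim(dff_blank)[1] < 1L) stop("at least one blank trial is required")
  blank_mean <- colMeans(dff_blank)        # frames x rows x cols
  out <- dff_stim
  for (tr in seq_len(dim(dff_stim)[1]))
    out[tr, , , ] <- dff_stim[tr, , , ] - blank_mean
  out
}

#' Average trials into a delta-f/f movie
#'
#' Frame-wise mean over trials; the per-trial corrected stacks are retained
#' on the returned object so across-trial SEMs remain computable downstream.
#'
#' @param dff 4-D corrected per-trial delta-f/f array.
#' @param acq the session's [AcquisitionSpec].
#' @param stim the [StimulusSpec] (or `NULL`).
#' @param condition,session_id labels.
#' @return A [DffMovie] with all frames and pixels initially valid.
#' @export
averageTrials <- function(dff, acq, stim = NULL, condition = "",
                          session_id = "") {
  if (length(dim(dff)) != 4L || dim(dff)[1] < 1L)
    stop("dff must be a non-empty 4-D per-trial array")
  DffMovie(
    data = colMeans(dff),
    time_ms = frameTimes(acq),
    valid_frames = rep(TRUE, acq@n_frames),
    valid_pixels = matrix(TRUE, acq@height_px, acq@width_px),
    n_trials = dim(dff)[1],
    trials = dff,
    acq = acq, stim = stim,
    condition = condition, session_id = session_id
  )
}

#' Mask the optical-stimulation frames
#'
#' For optostimulation, the frames at t = 0 and t = 10 ms are saturated by
#' the laser light artifact and are flagged invalid (their data set to `NA`).
#' ICMS produces no optical artifact, so no frames are removed; cross-modality
#' comparisons instead anchor at t >= 20 ms.  Idempotent.
#'
#' @param movie a [DffMovie].
#' @param modality `"opto"` or `"icms"`; defaults to the movie's stimulus.
#' @return The movie with updated `valid_frames`.
#' @export
maskStimulationFrames <- function(movie, modality = NULL) {
  stopifnot(is(movie, "DffMovie"))
  modality <- modality %||% (if (is.null(movie@stim)) "opto"
                             else movie@stim@modality)
  if (modality != "opto") return(movie)
  bad <- abs(movie@time_ms - 0) < 1e-6 | abs(movie@time_ms - 10) < 1e-6
  movie@valid_frames[bad] <- FALSE
  movie@data[bad, , ] <- NA_real_
  movie
}

#' Mask photobleached pixels near the fiber tip
#'
#' Laser light photobleaches the dye near the fiber tip, visible as pixels
#' with large negative delta-f/f immediately after laser offset.  Pixels
#' within `search_radius_um` of the stimulation site whose trial-averaged
#' signal falls below `neg_threshold` at any valid frame inside `window_ms`
#' are flagged invalid for all frames.
#'
#' @param movie a [DffMovie].
#' @param site_px stimulation site (row, col); defaults to the movie's
#'   stimulus site.
#' @param search_radius_um search radius around the site (um).
#' @param neg_threshold negative delta-f/f threshold (< 0).
#' @param window_ms length-2 window (ms) immediately after stimulus offset in
#'   which bleaching is detected.
#' @return The movie with updated `valid_pixels`.
#' @export
maskBleachedPixels <- function(movie, site_px = NULL, search_radius_um = 500,
                               neg_threshold = -2e-3,
                               window_ms = c(10, 40)) {
  stopifnot(is(movie, "DffMovie"))
  if (neg_threshold >= 0) stop("neg_threshold must be < 0")
  site_px <- site_px %||% movie@stim@site_px
  acq <- movie@acq
  if (site_px[1] < 1 || site_px[1] > acq@height_px ||
      site_px[2] < 1 || site_px[2] > acq@width_px)
    stop("site lies outside the frame")
  near <- distanceGrid(acq@height_px, acq@width_px, site_px, acq@pixel_um) <=
    search_radius_um + 1e-9
  frames <- which(movie@valid_frames & movie@time_ms >= window_ms[1] &
                    movie@time_ms <= window_ms[2])
  if (length(frames) == 0L) return(movie)
  sub <- movie@data[frames, , , drop = FALSE]
  dips <- apply(sub, c(2, 3), function(v) any(v < neg_threshold, na.rm = TRUE))
  bad <- near & dips
  if (any(bad)) {
    movie@valid_pixels[bad] <- FALSE
    for (k in seq_len(dim(movie@data)[1])) movie@data[k, , ][bad] <- NA_real_
  }
  movie
}

#' Full preprocessing chain for one condition
#'
#' Runs frame-zero division on the stimulated and blank stacks, subtracts the
#' blank mean, averages trials, and (for optostimulation) masks the
#' artifact frames and photobleached pixels.
#'
#' @param stimulated,blank [TrialStack]s of the stimulated and blank trials.
#' @param mask_frames,mask_bleach logical switches for the masking steps.
#' @param ... further arguments passed to [maskBleachedPixels()].
#' @return A [DffMovie].
#' @examples
#' p <- vsdPreset("short_exp")
#' ses <- simulateSession(AcquisitionSpec(), p$stim, p$resp, p$art,
#'                        3, 2, seed = 1)
#' mv <- preprocessSession(ses$stimulated, ses$blank)
#' mv
#' @export
preprocessSession <- function(stimulated, blank, mask_frames = TRUE,
                              mask_bleach = TRUE, ...) {
  if (is.null(blank) || !is(blank, "TrialStack"))
    stop("blank trials are required for blank subtraction")
  dff_s <- frameZeroDivide(stimulated)
  dff_b <- frameZeroDivide(blank)
  corr <- blankSubtract(dff_s, dff_b)
  movie <- averageTrials(corr, stimulated@acq, stim = stimulated@stim,
                         condition = stimulated@condition,
                         session_id = stimulated@session_id)
  is_opto <- !is.null(stimulated@stim) && stimulated@stim@modality == "opto"
  if (mask_frames) movie <- maskStimulationFrames(movie)
  if (mask_bleach && is_opto) movie <- maskBleachedPixels(movie, ...)
  movie
}
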