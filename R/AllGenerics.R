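## Accessors and show methods

#' Frame times relative to stimulation onset
#'
#' @param x an [AcquisitionSpec], [TrialStack] or [DffMovie].
#' @return Numeric vector of per-frame times in ms; the frame at
#'   `onset_frame` has t = 0.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "AcquisitionSpec", function(x) {
  (seq_len(x@n_frames) - x@onset_frame) * x@frame_ms
})

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "TrialStack", function(x) frameTimes(x@acq))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "DffMovie", function(x) x@time_ms)

#' Number of pre-stimulus baseline frames
#' @param x an [AcquisitionSpec].
#' @return Integer count of frames before stimulation onset.
#' @export
baselineFrames <- function(x) x@onset_frame - 1L

#' Number of trials
#' @param x a [TrialStack] or [DffMovie].
#' @return Integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname nTrials
#' @export
setMethod("nTrials", "TrialStack", function(x) dim(x@data)[1])

#' @rdname nTrials
#' @export
setMethod("nTrials", "DffMovie", function(x) x@n_trials)

#' Extract slot-like components of pipeline objects
#'
#' Read-only accessors: `acqSpec()` returns the acquisition geometry,
#' `stimSpec()` the stimulus description (`NULL` for blank stacks),
#' `movieData()` the delta-f/f array, `trialData()` the retained per-trial
#' delta-f/f array, `validFrames()`/`validPixels()` the masks, and
#' `conditionLabel()` the condition tag.
#'
#' @param x a pipeline object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("acqSpec", function(x) standardGeneric("acqSpec"))
#' @rdname accessors
#' @export
setMethod("acqSpec", "TrialStack", function(x) x@acq)
#' @rdname accessors
#' @export
setMethod("acqSpec", "DffMovie", function(x) x@acq)

#' @rdname accessors
#' @export
setGeneric("stimSpec", function(x) standardGeneric("stimSpec"))
#' @rdname accessors
#' @export
setMethod("stimSpec", "TrialStack", function(x) x@stim)
#' @rdname accessors
#' @export
setMethod("stimSpec", "DffMovie", function(x) x@stim)

#' @rdname accessors
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))
#' @rdname accessors
#' @export
setMethod("movieData", "DffMovie", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))
#' @rdname accessors
#' @export
setMethod("trialData", "TrialStack", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("trialData", "DffMovie", function(x) x@trials)

#' @rdname accessors
#' @export
setGeneric("validFrames", function(x) standardGeneric("validFrames"))
#' @rdname accessors
#' @export
setMethod("validFrames", "DffMovie", function(x) x@valid_frames)
#' @rdname accessors
#' @export
setMethod("validFrames", "SpaceTimeMap", function(x) x@valid_frames)

#' @rdname accessors
#' @export
setGeneric("validPixels", function(x) standardGeneric("validPixels"))
#' @rdname accessors
#' @export
setMethod("validPixels", "DffMovie", function(x) x@valid_pixels)

#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setMethod("conditionLabel", "TrialStack", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("conditionLabel", "DffMovie", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("conditionLabel", "SpaceTimeMap", function(x) x@condition)

#' Ring membership
#'
#' @param x a [RingSet].
#' @param ring integer ring index (1-based), or a vector of indices.
#' @return Integer matrix of (row, col) pixel coordinates belonging to the
#'   requested ring(s).
#' @export
setGeneric("ringPixels", function(x, ring) standardGeneric("ringPixels"))

#' @rdname ringPixels
#' @export
setMethod("ringPixels", "RingSet", function(x, ring) {
  which(!is.na(x@label) & x@label %in% ring, arr.ind = TRUE)
})

#' @rdname accessors
#' @export
setGeneric("nRings", function(x) standardGeneric("nRings"))
#' @rdname accessors
#' @export
setMethod("nRings", "RingSet", function(x) x@n_rings)
#' @rdname accessors
#' @export
setMethod("nRings", "SpaceTimeMap", function(x) nrow(x@values))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "SpaceTimeMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("mapValues", "DecayMap", function(x) x@times_ms)

setMethod("show", "AcquisitionSpec", function(object) {
  cat(sprintf("AcquisitionSpec: %d x %d px, %.0f um/px, %.0f ms/frame, %d frames (onset at frame %d)\n",
              object@height_px, object@width_px, object@pixel_um,
              object@frame_ms, object@n_frames, object@onset_frame))
})

setMethod("show", "StimulusSpec", function(object) {
  extra <- if (object@modality == "opto")
    sprintf("%.0f mW", object@power_mw %||% NA_real_)
  else
    sprintf("%.0f uA x %d pulses", object@current_ua %||% NA_real_,
            object@n_pulses)
  cat(sprintf("StimulusSpec: %s, %.0f ms pulse, %s, site (%g, %g)\n",
              object@modality, object@pulse_ms, extra,
              object@site_px[1], object@site_px[2]))
})

setMethod("show", "TrialStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialStack '%s': %d trials x %d frames x %d x %d px (%s)\n",
              object@condition, d[1], d[2], d[3], d[4],
              if (is.null(object@stim)) "blank" else object@stim@modality))
})

setMethod("show", "DffMovie", function(object) {
  d <- dim(object@data)
  cat(sprintf("DffMovie '%s': %d frames x %d x %d px, %d trials\n",
              object@condition, d[1], d[2], d[3], object@n_trials))
  cat(sprintf("  t = %g..%g ms; %d invalid frame(s), %d masked pixel(s)\n",
              min(object@time_ms), max(object@time_ms),
              sum(!object@valid_frames), sum(!object@valid_pixels)))
})

setMethod("show", "RingSet", function(object) {
  cat(sprintf("RingSet: %d rings of %g um around (%g, %g), to %g um\n",
              object@n_rings, object@step_um, object@center_px[1],
              object@center_px[2], max(object@distance_um)))
})

setMethod("show", "SpaceTimeMap", function(object) {
  cat(sprintf("SpaceTimeMap '%s' [%s]: %d rings x %d frames\n",
              object@condition, object@normalization, nrow(object@values),
              ncol(object@values)))
})

setMethod("show", "DecayMap", function(object) {
  cat(sprintf("DecayMap '%s': threshold %.0f%% of peak, window [%g, %g] ms, %d pixel(s) never crossed\n",
              object@condition, 100 * object@threshold_fraction,
              object@t_start_ms, object@t_end_ms, object@n_not_crossed))
})

setMethod("show", "YFPImage", function(object) {
  cat(sprintf("YFPImage '%s' (%s): %d x %d px, %s\n",
              object@animal, object@group, nrow(object@data),
              ncol(object@data),
              if (object@normalized) "normalized" else "raw"))
})
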