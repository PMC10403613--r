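#' @import methods
NULL

## ---------------------------------------------------------------------------
## Parameter objects for acquisition, stimulation, response and artifacts
## ---------------------------------------------------------------------------

#' Acquisition geometry and timing of a VSDI session
#'
#' Describes the camera geometry and frame clock of a voltage-sensitive dye
#' imaging (VSDI) session: a `height_px` x `width_px` sensor sampling a
#' cortical area at `pixel_um` micrometers per pixel and `frame_ms`
#' milliseconds per frame.  `onset_frame` is the (1-based) index of the frame
#' at t = 0 ms, i.e. stimulation onset; frames `1..onset_frame-1` are the
#' pre-stimulus baseline used for frame-zero division, so at least one
#' baseline frame is required.
#'
#' The defaults correspond to a 100 x 100 pixel image of a 5 x 5 mm cortical
#' area (50 um/pixel) sampled at 100 Hz.
#'
#' @param height_px,width_px image dimensions in pixels.
#' @param pixel_um pixel pitch in micrometers.
#' @param frame_ms frame duration in milliseconds.
#' @param n_frames number of frames per trial.
#' @param onset_frame 1-based index of the frame at t = 0 ms.
#' @return An `AcquisitionSpec` object.
#' @examples
#' acq <- AcquisitionSpec()
#' frameTimes(acq)[1:8]
#' @export AcquisitionSpec
#' @exportClass AcquisitionSpec
AcquisitionSpec <- setClass("AcquisitionSpec",
  slots = c(
    height_px   = "integer",
    width_px    = "integer",
    pixel_um    = "numeric",
    frame_ms    = "numeric",
    n_frames    = "integer",
    onset_frame = "integer"
  ),
  prototype = list(
    height_px = 100L, width_px = 100L, pixel_um = 50, frame_ms = 10,
    n_frames = 21L, onset_frame = 6L
  )
)

setValidity("AcquisitionSpec", function(object) {
  msg <- character()
  if (object@pixel_um <= 0) msg <- c(msg, "pixel_um must be > 0")
  if (object@frame_ms <= 0) msg <- c(msg, "frame_ms must be > 0")
  if (object@height_px < 1 || object@width_px < 1)
    msg <- c(msg, "image dimensions must be >= 1 pixel")
  if (object@onset_frame < 2L)
    msg <- c(msg, "onset_frame must be >= 2 (at least one pre-stimulus frame is needed for frame-zero division)")
  if (object@onset_frame > object@n_frames)
    msg <- c(msg, "onset_frame must not exceed n_frames")
  if (length(msg)) msg else TRUE
})

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Stimulus description
#'
#' Describes one stimulation condition: `modality` is `"opto"` (laser
#' activation of ChR2-expressing neurons) or `"icms"` (intracortical
#' microstimulation).  The optostimulation conditions are single square
#' pulses of 2, 5 or 10 ms at 15 mW; ICMS uses a 10-pulse 500 Hz train
#' of 80 uA biphasic pulses (20 ms total).  `site_px` is the (row, col) pixel
#' under the fiber tip or electrode.
#'
#' @param modality `"opto"` or `"icms"`.
#' @param pulse_ms stimulus duration in ms (total train duration for ICMS).
#' @param power_mw laser power (opto), or `NULL`.
#' @param current_ua pulse current in microamperes (ICMS), or `NULL`.
#' @param n_pulses,rate_hz train description (ICMS).
#' @param site_px numeric length-2 (row, col) stimulation site.
#' @return A `StimulusSpec` object.
#' @export StimulusSpec
#' @exportClass StimulusSpec
StimulusSpec <- setClass("StimulusSpec",
  slots = c(
    modality   = "character",
    pulse_ms   = "numeric",
    power_mw   = "numericOrNULL",
    current_ua = "numericOrNULL",
    n_pulses   = "integer",
    rate_hz    = "numericOrNULL",
    site_px    = "numeric"
  ),
  prototype = list(
    modality = "opto", pulse_ms = 10, power_mw = 15, current_ua = NULL,
    n_pulses = 1L, rate_hz = NULL, site_px = c(50, 50)
  )
)

setValidity("StimulusSpec", function(object) {
  msg <- character()
  if (!object@modality %in% c("opto", "icms"))
    msg <- c(msg, "modality must be 'opto' or 'icms'")
  if (object@pulse_ms <= 0) msg <- c(msg, "pulse_ms must be > 0")
  if (length(object@site_px) != 2L)
    msg <- c(msg, "site_px must be (row, col)")
  if (length(msg)) msg else TRUE
})

setClassUnion("StimulusSpecOrNULL", c("StimulusSpec", "NULL"))

#' Evoked-response model of the synthetic generator
#'
#' Parameterizes the noiseless evoked delta-f/f field
#' \deqn{R(x, y, t) = A \, s(p) \, T(t) \, \exp(-d(x,y)^2 / 2\sigma(t)^2)}
#' used by [simulateSession()].  `amplitude` is the peak delta-f/f at the
#' response center at the reference pulse duration; `s(p) =
#' (p/pulse_ref_ms)^pulse_gamma` scales it with pulse duration.  The temporal
#' kernel T(t) rises with channel-opening kinetics (`tau_open_ms`, ChR2(H134R)
#' opening tau ~1.92 ms) to a peak pinned at `t_peak_ms` (20 ms, the first
#' artifact-free frame, where all analyses anchor), then decays as a mixture
#' of a fast and a slow exponential, `w_fast exp(-(t-t_peak)/tau_fast_ms) +
#' w_slow exp(-(t-t_peak)/tau_slow_ms)` (`w_fast + w_slow = 1`), emulating the
#' early fast decay followed by a slower decline seen in the recordings; the
#' ChR2 closing tau (~17.9 ms) informs the fast component.  The spatial
#' Gaussian width grows linearly after the peak, `sigma(t) = sigma0_um +
#' speed_um_ms * max(t - t_peak, 0)`, emulating lateral spread.
#'
#' @param amplitude peak delta-f/f (unitless) at the reference pulse.
#' @param sigma0_um initial spatial Gaussian width (um).
#' @param speed_um_ms lateral spread speed (um/ms) after the peak.
#' @param tau_open_ms,tau_close_ms channel opening/closing time constants (ms).
#' @param w_fast,w_slow decay-component weights, summing to 1.
#' @param tau_fast_ms,tau_slow_ms decay time constants (ms).
#' @param t_peak_ms time of the temporal peak (ms); 20 ms by convention.
#' @param pulse_gamma,pulse_ref_ms pulse-duration scaling exponent and
#'   reference duration for `s(p)`.
#' @return A `ResponseModel` object.
#' @seealso [vsdPreset()] for the calibrated presets.
#' @export ResponseModel
#' @exportClass ResponseModel
ResponseModel <- setClass("ResponseModel",
  slots = c(
    amplitude    = "numeric",
    sigma0_um    = "numeric",
    speed_um_ms  = "numeric",
    tau_open_ms  = "numeric",
    tau_close_ms = "numeric",
    w_fast       = "numeric",
    w_slow       = "numeric",
    tau_fast_ms  = "numeric",
    tau_slow_ms  = "numeric",
    t_peak_ms    = "numeric",
    pulse_gamma  = "numeric",
    pulse_ref_ms = "numeric"
  ),
  prototype = list(
    amplitude = 3e-3, sigma0_um = 400, speed_um_ms = 2,
    tau_open_ms = 1.92, tau_close_ms = 17.9,
    w_fast = 0.6, w_slow = 0.4, tau_fast_ms = 18, tau_slow_ms = 100,
    t_peak_ms = 20, pulse_gamma = 0.4, pulse_ref_ms = 10
  )
)

setValidity("ResponseModel", function(object) {
  msg <- character()
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@w_fast < 0 || object@w_slow < 0)
    msg <- c(msg, "decay weights must be non-negative")
  if (abs(object@w_fast + object@w_slow - 1) > 1e-8)
    msg <- c(msg, "w_fast + w_slow must equal 1")
  taus <- c(object@tau_open_ms, object@tau_close_ms, object@tau_fast_ms,
            object@tau_slow_ms)
  if (any(taus <= 0)) msg <- c(msg, "all time constants must be > 0")
  if (object@sigma0_um <= 0) msg <- c(msg, "sigma0_um must be > 0")
  if (length(msg)) msg else TRUE
})

#' Artifact and noise model of the synthetic generator
#'
#' Nuisance components added by [simulateSession()] on top of the evoked
#' response: a frame-wide additive laser artifact (`laser_gain`, delta-f/f
#' units) during the frames overlapping the optical pulse; a photobleach spot
#' (top-hat of radius `bleach_radius_um` around the stimulation site, additive
#' offset `bleach_depth` <= 0 after stimulus offset); a slow linear
#' fluorescence drift (`drift_slope` per frame); a heartbeat oscillation
#' shared deterministically between stimulated and blank trials (so blank
#' subtraction removes it); and per-pixel per-frame Gaussian camera noise on
#' raw fluorescence (`noise_sd`, fluorescence units, baseline ~1000).
#'
#' @param laser_gain additive delta-f/f offset during optical-pulse frames.
#' @param bleach_radius_um radius of the photobleach spot (um).
#' @param bleach_depth negative delta-f/f offset inside the spot after offset.
#' @param drift_slope fractional fluorescence change per frame.
#' @param heartbeat_hz,heartbeat_amp heartbeat frequency (Hz) and fractional
#'   amplitude; 6 Hz default (urethane-anesthetized rat range).
#' @param noise_sd Gaussian noise SD on raw fluorescence.
#' @return An `ArtifactModel` object.
#' @export ArtifactModel
#' @exportClass ArtifactModel
ArtifactModel <- setClass("ArtifactModel",
  slots = c(
    laser_gain       = "numeric",
    bleach_radius_um = "numeric",
    bleach_depth     = "numeric",
    drift_slope      = "numeric",
    heartbeat_hz     = "numeric",
    heartbeat_amp    = "numeric",
    noise_sd         = "numeric"
  ),
  prototype = list(
    laser_gain = 0.05, bleach_radius_um = 150, bleach_depth = -8e-3,
    drift_slope = -1e-4, heartbeat_hz = 6, heartbeat_amp = 5e-4,
    noise_sd = 1.5
  )
)

setValidity("ArtifactModel", function(object) {
  msg <- character()
  if (object@bleach_depth > 0) msg <- c(msg, "bleach_depth must be <= 0")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@bleach_radius_um < 0) msg <- c(msg, "bleach_radius_um must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Raw fluorescence trials of one condition
#'
#' Holds the raw fluorescence data of all trials of one condition of one
#' session as a 4-D array `trials x frames x rows x cols` (arbitrary
#' fluorescence units), together with the acquisition geometry and, for
#' stimulated conditions, the stimulus description (`stim = NULL` marks blank,
#' i.e. no-stimulation, trials).
#'
#' @param data 4-D numeric array, `trials x frames x rows x cols`.
#' @param acq an [AcquisitionSpec].
#' @param stim a [StimulusSpec], or `NULL` for blank trials.
#' @param session_id,condition character labels.
#' @return A `TrialStack` object.
#' @export TrialStack
#' @exportClass TrialStack
TrialStack <- setClass("TrialStack",
  slots = c(
    data       = "array",
    acq        = "AcquisitionSpec",
    stim       = "StimulusSpecOrNULL",
    session_id = "character",
    condition  = "character"
  ),
  prototype = list(session_id = "", condition = "")
)

setValidity("TrialStack", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 4L)
    return("data must be a 4-D array (trials x frames x rows x cols)")
  if (d[2] != object@acq@n_frames)
    msg <- c(msg, "frame count of data does not match acq@n_frames")
  if (d[3] != object@acq@height_px || d[4] != object@acq@width_px)
    msg <- c(msg, "image dimensions of data do not match acq")
  if (length(msg)) msg else TRUE
})

#' Trial-averaged delta-f/f movie
#'
#' The preprocessed signal of one condition: a 3-D array
#' `frames x rows x cols` of trial-averaged delta-f/f, a millisecond time axis
#' relative to stimulation onset, validity masks for frames and pixels, and
#' the retained per-trial corrected stacks (`trials`,
#' `trials x frames x rows x cols`) from which across-trial SEMs are computed
#' downstream.  Invalidated frames/pixels carry `NA` in `data` (never a silent
#' zero) in addition to being flagged in the masks; all downstream averages
#' are mask-aware.
#'
#' @seealso [preprocessSession()], [maskStimulationFrames()],
#'   [maskBleachedPixels()]
#' @export
#' @exportClass DffMovie
DffMovie <- setClass("DffMovie",
  slots = c(
    data         = "array",
    time_ms      = "numeric",
    valid_frames = "logical",
    valid_pixels = "matrix",
    n_trials     = "integer",
    trials       = "array",
    acq          = "AcquisitionSpec",
    stim         = "StimulusSpecOrNULL",
    condition    = "character",
    session_id   = "character"
  ),
  prototype = list(condition = "", session_id = "")
)

setValidity("DffMovie", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    return("data must be a 3-D array (frames x rows x cols)")
  if (length(object@time_ms) != d[1])
    msg <- c(msg, "time_ms length must match the number of frames")
  if (length(object@valid_frames) != d[1])
    msg <- c(msg, "valid_frames length must match the number of frames")
  if (!all(dim(object@valid_pixels) == d[2:3]))
    msg <- c(msg, "valid_pixels must be rows x cols")
  on <- object@acq@onset_frame
  if (length(object@time_ms) >= on && abs(object@time_ms[on]) > 1e-9)
    msg <- c(msg, "time_ms at onset_frame must be 0")
  if (length(msg)) msg else TRUE
})

#' Concentric annulus set around a response center
#'
#' Partition of the image into concentric non-overlapping annuli ("rings")
#' around a center pixel.  Ring k contains the pixels whose center-to-center
#' distance d (um) satisfies `(k-1)*step_um < d <= k*step_um`; with the
#' defaults (50 um steps to a 2 mm radius) this yields exactly 40 disjoint
#' rings whose union is every pixel with `0 < d <= 2000` um.  The "central
#' ring" used for normalization is the mean over rings 1-5.
#'
#' @seealso [buildRings()], [spaceTimeMap()]
#' @export
#' @exportClass RingSet
RingSet <- setClass("RingSet",
  slots = c(
    label         = "matrix",
    center_px     = "numeric",
    step_um       = "numeric",
    n_rings       = "integer",
    distance_um   = "numeric",
    central_rings = "integer",
    pixel_um      = "numeric"
  )
)

setValidity("RingSet", function(object) {
  msg <- character()
  if (length(object@center_px) != 2L) msg <- c(msg, "center_px must be (row, col)")
  if (object@n_rings < 1L) msg <- c(msg, "n_rings must be >= 1")
  if (length(object@distance_um) != object@n_rings)
    msg <- c(msg, "distance_um must have one outer edge per ring")
  lab <- object@label[!is.na(object@label)]
  if (length(lab) && (min(lab) < 1L || max(lab) > object@n_rings))
    msg <- c(msg, "ring labels out of range")
  if (length(msg)) msg else TRUE
})

#' Ring-by-frame space-time map
#'
#' Mean delta-f/f per ring per frame (`values`, `n_rings x n_frames`), plus
#' the central-ring row (`center`, mean over rings 1-5 per frame), the time
#' axis, the outer-edge distance of each ring, and a normalization tag
#' (`"raw"` or `"norm_to_center_t20"`).
#'
#' @seealso [spaceTimeMap()], [summedActivation()], [spatialProfile()],
#'   [ringTimeCourse()]
#' @export
#' @exportClass SpaceTimeMap
SpaceTimeMap <- setClass("SpaceTimeMap",
  slots = c(
    values        = "matrix",
    center        = "numeric",
    time_ms       = "numeric",
    distance_um   = "numeric",
    valid_frames  = "logical",
    normalization = "character",
    condition     = "character",
    session_id    = "character"
  ),
  prototype = list(normalization = "raw", condition = "", session_id = "")
)

setValidity("SpaceTimeMap", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@time_ms))
    msg <- c(msg, "values must have one column per frame")
  if (nrow(object@values) != length(object@distance_um))
    msg <- c(msg, "values must have one row per ring")
  if (length(object@center) != length(object@time_ms))
    msg <- c(msg, "center must have one value per frame")
  if (length(msg)) msg else TRUE
})

#' Per-pixel decay-time-to-threshold map
#'
#' For each pixel, the first time (ms, sub-frame precision by linear
#' interpolation) after the peak frame at which the delta-f/f signal falls
#' below `threshold_fraction` of that pixel's peak (the value at the anchor
#' frame, t = 20 ms).  Pixels that are invalid, have non-positive peak, or
#' never cross within the analysis window are `NA` in `times_ms`;
#' `n_not_crossed` counts the valid pixels that never crossed.
#'
#' @seealso [decayTimeMap()], [decayDistributions()]
#' @export
#' @exportClass DecayMap
DecayMap <- setClass("DecayMap",
  slots = c(
    times_ms           = "matrix",
    threshold_fraction = "numeric",
    peak               = "matrix",
    valid              = "matrix",
    t_start_ms         = "numeric",
    t_end_ms           = "numeric",
    n_not_crossed      = "integer",
    condition          = "character",
    session_id         = "character"
  ),
  prototype = list(condition = "", session_id = "")
)

setValidity("DecayMap", function(object) {
  msg <- character()
  if (object@threshold_fraction <= 0 || object@threshold_fraction >= 1)
    msg <- c(msg, "threshold_fraction must be in (0, 1)")
  if (!all(dim(object@times_ms) == dim(object@peak)))
    msg <- c(msg, "times_ms and peak must have identical dimensions")
  tms <- object@times_ms[!is.na(object@times_ms)]
  if (length(tms) && any(tms < object@t_start_ms - 1e-9))
    msg <- c(msg, "decay times cannot precede the anchor frame")
  if (length(msg)) msg else TRUE
})

#' Single-frame YFP expression image
#'
#' An in-vivo fluorescence image of opsin-YFP expression with a chamber mask
#' (pixels inside the imaging chamber), used to quantify expression area via
#' min-max normalization and a 2-SD threshold count.
#'
#' @seealso [normalizeYfp()], [countExpressingPixels()]
#' @export
#' @exportClass YFPImage
YFPImage <- setClass("YFPImage",
  slots = c(
    data       = "matrix",
    mask       = "matrix",
    normalized = "logical",
    animal     = "character",
    group      = "character"
  ),
  prototype = list(normalized = FALSE, animal = "", group = "")
)

setValidity("YFPImage", function(object) {
  msg <- character()
  if (!all(dim(object@data) == dim(object@mask)))
    msg <- c(msg, "mask must match data dimensions")
  if (object@normalized) {
    v <- object@data[object@mask]
    if (length(v) && (min(v) < -1e-6 || max(v) > 1 + 1e-6))
      msg <- c(msg, "normalized image must lie in [0, 1] within the mask")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic session
#'
#' The generator parameters and the noiseless evoked delta-f/f movie
#' (`frames x rows x cols`) of a synthetic session, enabling
#' parameter-recovery and end-to-end oracle tests against the pipeline.
#'
#' @export
#' @exportClass GroundTruth
GroundTruth <- setClass("GroundTruth",
  slots = c(
    resp      = "ResponseModel",
    art       = "ArtifactModel",
    stim      = "StimulusSpec",
    acq       = "AcquisitionSpec",
    center_px = "numeric",
    dff       = "array",
    seed      = "integer"
  )
)
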