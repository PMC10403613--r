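## ---------------------------------------------------------------------------
## Synthetic-session generator: stimulated + blank trial stacks with ground
## truth, emulating mesoscale VSDI of laser- or ICMS-evoked cortical activity.
## ---------------------------------------------------------------------------

#' Temporal kernel of the evoked response
#'
#' Evaluates the unitless temporal kernel T(t) of a [ResponseModel]: zero for
#' t < 0, a channel-opening rise `(1 - exp(-t/tau_open)) /
#' (1 - exp(-t_peak/tau_open))` on `[0, t_peak]` (so T(t_peak) = 1 exactly),
#' and for t > t_peak the two-component decay
#' `w_fast exp(-(t - t_peak)/tau_fast) + w_slow exp(-(t - t_peak)/tau_slow)`.
#'
#' @param resp a [ResponseModel].
#' @param t_ms numeric vector of times (ms) relative to stimulation onset.
#' @return Numeric vector of kernel values, peaking at exactly 1 at
#'   `t_peak_ms`.
#' @export
temporalKernel <- function(resp, t_ms) {
  tp <- resp@t_peak_ms
  out <- numeric(length(t_ms))
  rise <- t_ms >= 0 & t_ms <= tp
  out[rise] <- (1 - exp(-t_ms[rise] / resp@tau_open_ms)) /
    (1 - exp(-tp / resp@tau_open_ms))
  dec <- t_ms > tp
  s <- t_ms[dec] - tp
  out[dec] <- resp@w_fast * exp(-s / resp@tau_fast_ms) +
    resp@w_slow * exp(-s / resp@tau_slow_ms)
  out
}

#' Pulse-duration amplitude scaling
#'
#' Saturating power-law scaling `s(p) = (p / pulse_ref_ms)^pulse_gamma` of
#' the peak amplitude with pulse duration, calibrated so the normalized
#' grand-average peaks of the 2/5/10 ms conditions reproduce the observed
#' ratios (short expression ~0.4/0.7/1, long expression ~0.6/0.8/1).
#' Monotone non-decreasing in `pulse_ms`.
#'
#' @param resp a [ResponseModel].
#' @param pulse_ms pulse duration (ms).
#' @return Scalar scaling factor; 1 at the reference duration.
#' @export
pulseScale <- function(resp, pulse_ms) {
  (pulse_ms / resp@pulse_ref_ms)^resp@pulse_gamma
}

#' Noiseless evoked delta-f/f field
#'
#' Evaluates `R(x, y, t) = A s(p) T(t) exp(-d^2 / (2 sigma(t)^2))` on the
#' acquisition grid, where d is the pixel-center distance (um) to the
#' stimulation site and `sigma(t) = sigma0 + speed * max(t - t_peak, 0)`.
#'
#' @param acq an [AcquisitionSpec].
#' @param stim a [StimulusSpec] (supplies pulse duration and site).
#' @param resp a [ResponseModel].
#' @return 3-D array `frames x rows x cols` of noiseless delta-f/f.
#' @export
responseField <- function(acq, stim, resp) {
  t_ms <- frameTimes(acq)
  amp <- resp@amplitude * pulseScale(resp, stim@pulse_ms)
  Tt <- temporalKernel(resp, t_ms)
  d2 <- distanceGrid(acq@height_px, acq@width_px, stim@site_px, acq@pixel_um)^2
  out <- array(0, c(acq@n_frames, acq@height_px, acq@width_px))
  for (k in seq_len(acq@n_frames)) {
    if (Tt[k] == 0) next
    sig <- resp@sigma0_um + resp@speed_um_ms * max(t_ms[k] - resp@t_peak_ms, 0)
    out[k, , ] <- amp * Tt[k] * exp(-d2 / (2 * sig^2))
  }
  out
}

#' Calibrated generator presets for the three stimulation conditions
#'
#' Returns the stimulus, response and artifact models emulating one of the
#' study conditions: `"short_exp"` (3-4 weeks of opsin expression, weak and
#' fast-decaying responses), `"long_exp"` (8 weeks, stronger responses with a
#' substantial slow decay component), or `"icms"` (electrical
#' microstimulation, the strongest and most widespread responses, slowest
#' decay, and no optical artifacts).  Peak amplitudes are the observed
#' grand-average t = 20 ms values (1.4, 3.6, 5.1 x 1e-3 delta-f/f); the
#' presets preserve the orderings amplitude(short) < amplitude(long) <
#' amplitude(icms), w_slow(short) < w_slow(long) <= w_slow(icms), and
#' increasing spatial extent.
#'
#' @param name `"short_exp"`, `"long_exp"` or `"icms"`.
#' @param pulse_ms pulse duration override (ms); defaults to 10 for
#'   optostimulation and 20 (the full train) for ICMS.
#' @param site_px stimulation-site pixel (row, col).
#' @return A list with elements `stim` ([StimulusSpec]), `resp`
#'   ([ResponseModel]) and `art` ([ArtifactModel]).
#' @examples
#' p <- vsdPreset("long_exp", pulse_ms = 5)
#' p$resp
#' @export
vsdPreset <- function(name = c("short_exp", "long_exp", "icms"),
                      pulse_ms = NULL, site_px = c(50, 50)) {
  name <- match.arg(name)
  if (name == "icms") {
    stim <- StimulusSpec(modality = "icms", pulse_ms = pulse_ms %||% 20,
                         power_mw = NULL, current_ua = 80, n_pulses = 10L,
                         rate_hz = 500, site_px = site_px)
    resp <- ResponseModel(amplitude = 5.1e-3, sigma0_um = 600,
                          speed_um_ms = 3, tau_open_ms = 0.5,
                          tau_close_ms = 17.9,
                          w_fast = 0.45, w_slow = 0.55,
                          tau_fast_ms = 20, tau_slow_ms = 140,
                          t_peak_ms = 20, pulse_gamma = 0.3,
                          pulse_ref_ms = 20)
    art <- ArtifactModel(laser_gain = 0, bleach_radius_um = 0,
                         bleach_depth = 0, drift_slope = -1e-4,
                         heartbeat_hz = 6, heartbeat_amp = 5e-4,
                         noise_sd = 1.5)
  } else {
    stim <- StimulusSpec(modality = "opto", pulse_ms = pulse_ms %||% 10,
                         power_mw = 15, current_ua = NULL, n_pulses = 1L,
                         rate_hz = NULL, site_px = site_px)
    if (name == "short_exp") {
      resp <- ResponseModel(amplitude = 1.4e-3, sigma0_um = 300,
                            speed_um_ms = 1, tau_open_ms = 1.92,
                            tau_close_ms = 17.9,
                            w_fast = 0.95, w_slow = 0.05,
                            tau_fast_ms = 12, tau_slow_ms = 80,
                            t_peak_ms = 20, pulse_gamma = 0.57,
                            pulse_ref_ms = 10)
    } else {
      resp <- ResponseModel(amplitude = 3.6e-3, sigma0_um = 450,
                            speed_um_ms = 2, tau_open_ms = 1.92,
                            tau_close_ms = 17.9,
                            w_fast = 0.55, w_slow = 0.45,
                            tau_fast_ms = 18, tau_slow_ms = 100,
                            t_peak_ms = 20, pulse_gamma = 0.32,
                            pulse_ref_ms = 10)
    }
    art <- ArtifactModel(laser_gain = 0.05, bleach_radius_um = 150,
                         bleach_depth = -8e-3, drift_slope = -1e-4,
                         heartbeat_hz = 6, heartbeat_amp = 5e-4,
                         noise_sd = 1.5)
  }
  list(stim = stim, resp = resp, art = art)
}

#' Simulate one synthetic VSDI session
#'
#' Generates raw fluorescence trial stacks for one stimulated condition plus
#' matched blank (no-stimulation) trials, with known ground truth.  Raw
#' fluorescence is
#' \deqn{F(x, y, t) = F_0(x, y) (1 + drift(t) + heartbeat(t) + R(x, y, t) +
#'   laser(t) + bleach(x, y, t)) + \epsilon}
#' where R is the evoked field of [responseField()] (zero in blank trials),
#' drift and heartbeat are deterministic and identical across stimulated and
#' blank trials (so blank subtraction removes them), the frame-wide laser
#' artifact is added during frames overlapping the optical pulse and the
#' top-hat photobleach spot after stimulus offset (both only for
#' `modality = "opto"` in stimulated trials), and epsilon is i.i.d. Gaussian
#' camera noise on raw fluorescence.  F0 is 1000 fluorescence units with mild
#' radial vignetting; only ratios matter downstream.  Identical inputs and
#' seed give bitwise-identical stacks.
#'
#' @param acq an [AcquisitionSpec].
#' @param stim a [StimulusSpec]; the site must lie inside the frame.
#' @param resp a [ResponseModel].
#' @param art an [ArtifactModel].
#' @param n_stim_trials,n_blank_trials trial counts (>= 1).
#' @param seed integer RNG seed (caller's RNG state is restored).
#' @param session_id,condition labels stored on the stacks.
#' @return A list with `stimulated` and `blank` [TrialStack]s and `truth`
#'   (a [GroundTruth] holding the noiseless evoked delta-f/f movie).
#' @examples
#' p <- vsdPreset("short_exp")
#' acq <- AcquisitionSpec()
#' ses <- simulateSession(acq, p$stim, p$resp, p$art, 3, 2, seed = 1)
#' ses$stimulated
#' @export
simulateSession <- function(acq, stim, resp, art,
                            n_stim_trials, n_blank_trials, seed = NULL,
                            session_id = "s1", condition = "stim") {
  stopifnot(is(acq, "AcquisitionSpec"), is(stim, "StimulusSpec"),
            is(resp, "ResponseModel"), is(art, "ArtifactModel"))
  if (n_stim_trials < 1 || n_blank_trials < 1)
    stop("trial counts must be >= 1")
  if (stim@site_px[1] < 1 || stim@site_px[1] > acq@height_px ||
      stim@site_px[2] < 1 || stim@site_px[2] > acq@width_px)
    stop("stimulation site lies outside the frame")

  nf <- acq@n_frames; nr <- acq@height_px; nc <- acq@width_px
  t_ms <- frameTimes(acq)

  ## baseline fluorescence: 1000 a.u. with mild radial vignetting
  dc <- distanceGrid(nr, nc, c((nr + 1) / 2, (nc + 1) / 2), 1)
  F0 <- 1000 * (1 - 0.05 * (dc / max(dc))^2)

  drift <- art@drift_slope * (seq_len(nf) - 1)
  heart <- art@heartbeat_amp * sin(2 * pi * art@heartbeat_hz * t_ms / 1000)

  R <- responseField(acq, stim, resp)

  ## shared (stim + blank) multiplicative component
  base <- array(0, c(nf, nr, nc))
  for (k in seq_len(nf)) base[k, , ] <- 1 + drift[k] + heart[k]

  ## stimulated-only components
  stim_part <- R
  if (stim@modality == "opto") {
    laser_frames <- which(t_ms >= 0 & t_ms <= stim@pulse_ms)
    if (art@laser_gain != 0)
      stim_part[laser_frames, , ] <- stim_part[laser_frames, , ] + art@laser_gain
    if (art@bleach_radius_um > 0 && art@bleach_depth < 0) {
      spot <- distanceGrid(nr, nc, stim@site_px, acq@pixel_um) <=
        art@bleach_radius_um + 1e-9
      post <- which(t_ms > stim@pulse_ms)
      for (k in post)
        stim_part[k, , ][spot] <- stim_part[k, , ][spot] + art@bleach_depth
    }
  }

  F0rep <- aperm(array(F0, c(nr, nc, nf)), c(3, 1, 2))
  mk_stack <- function(n, with_stim) {
    det <- F0rep * (base + if (with_stim) stim_part else 0)
    out <- array(0, c(n, nf, nr, nc))
    for (tr in seq_len(n)) {
      eps <- if (art@noise_sd > 0)
        array(stats::rnorm(nf * nr * nc, sd = art@noise_sd), c(nf, nr, nc))
      else 0
      out[tr, , , ] <- det + eps
    }
    out
  }

  res <- withSeed(seed, {
    s <- mk_stack(n_stim_trials, TRUE)
    b <- mk_stack(n_blank_trials, FALSE)
    list(s = s, b = b)
  })

  truth <- GroundTruth(resp = resp, art = art, stim = stim, acq = acq,
                       center_px = stim@site_px, dff = R,
                       seed = as.integer(seed %||% NA_integer_))
  list(
    stimulated = TrialStack(data = res$s, acq = acq, stim = stim,
                            session_id = session_id, condition = condition),
    blank = TrialStack(data = res$b, acq = acq, stim = NULL,
                       session_id = session_id, condition = "blank"),
    truth = truth
  )
}

#' Simulate an in-vivo YFP expression image
#'
#' Single-frame fluorescence image with a bright top-hat patch (radius
#' `extent_um` around `center_px`, additive level `level`) on a noisy uniform
#' background, emulating in-vivo imaging of opsin-YFP expression through the
#' cranial window.
#'
#' @param acq an [AcquisitionSpec] (geometry only).
#' @param center_px patch center (row, col).
#' @param extent_um patch radius in um; must fit inside the frame.
#' @param level patch fluorescence above background.
#' @param background_sd Gaussian noise SD.
#' @param seed integer RNG seed.
#' @param background background fluorescence level.
#' @param animal,group labels.
#' @return A raw (un-normalized) [YFPImage] whose chamber mask is the full
#'   frame.
#' @export
simulateYfpImage <- function(acq, center_px, extent_um, level,
                             background_sd = 0.02, seed = NULL,
                             background = 0.2, animal = "", group = "") {
  if (extent_um <= 0) stop("extent_um must be > 0")
  half_um <- min(acq@height_px, acq@width_px) / 2 * acq@pixel_um
  if (extent_um > half_um)
    stop("extent_um larger than the frame")
  nr <- acq@height_px; nc <- acq@width_px
  inside <- distanceGrid(nr, nc, center_px, acq@pixel_um) <= extent_um + 1e-9
  img <- withSeed(seed, {
    m <- matrix(background, nr, nc)
    if (background_sd > 0)
      m <- m + matrix(stats::rnorm(nr * nc, sd = background_sd), nr, nc)
    m[inside] <- m[inside] + level
    m
  })
  YFPImage(data = img, mask = matrix(TRUE, nr, nc), normalized = FALSE,
           animal = animal, group = group)
}
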