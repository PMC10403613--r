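## Shared fixtures: small geometries and hand-built containers so most tests
## run on tiny arrays.

tinyAcq <- function(h = 20L, w = 20L, n_frames = 12L, onset = 3L,
                    pixel_um = 50, frame_ms = 10) {
  AcquisitionSpec(height_px = as.integer(h), width_px = as.integer(w),
                  pixel_um = pixel_um, frame_ms = frame_ms,
                  n_frames = as.integer(n_frames),
                  onset_frame = as.integer(onset))
}

## DffMovie straight from a frames x rows x cols array (all valid),
## replicating it n_trials times in the trials slot.
movieFromArray <- function(arr, acq, n_trials = 1L, stim = NULL,
                           condition = "test") {
  trials <- array(0, c(n_trials, dim(arr)))
  for (tr in seq_len(n_trials)) trials[tr, , , ] <- arr
  DffMovie(data = arr, time_ms = frameTimes(acq),
           valid_frames = rep(TRUE, dim(arr)[1]),
           valid_pixels = matrix(TRUE, dim(arr)[2], dim(arr)[3]),
           n_trials = as.integer(n_trials), trials = trials,
           acq = acq, stim = stim, condition = condition, session_id = "t")
}

## Movie whose every pixel follows the same time course `vals`.
movieFromTimecourse <- function(vals, acq) {
  arr <- array(rep(vals, times = acq@height_px * acq@width_px),
               c(length(vals), acq@height_px, acq@width_px))
  movieFromArray(arr, acq)
}

## Artifact-free, noise-free artifact model.
cleanArt <- function() {
  ArtifactModel(laser_gain = 0, bleach_radius_um = 0, bleach_depth = 0,
                drift_slope = 0, heartbeat_hz = 6, heartbeat_amp = 0,
                noise_sd = 0)
}

## Time-course data frame from a value vector.
tcFromValues <- function(time_ms, values, condition = "tc") {
  data.frame(time_ms = time_ms, value = values, sem = 0,
             n_trials = 1L, condition = condition, session_id = "t",
             normalization = "raw", stringsAsFactors = FALSE)
}

frameAtOracle <- function(time_ms, t) which(abs(time_ms - t) < 1e-9)

## Independent pixel-center distance map (um), by explicit double loop.
distanceGridOracle <- function(acq, center_px) {
  m <- matrix(0, acq@height_px, acq@width_px)
  for (r in seq_len(acq@height_px))
    for (cc in seq_len(acq@width_px))
      m[r, cc] <- acq@pixel_um *
        sqrt((r - center_px[1])^2 + (cc - center_px[2])^2)
  m
}

## Exact two-sided rank-sum p-value by enumeration of all group assignments.
ranksumEnumP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1, simplify = FALSE)
  us <- vapply(idx, function(i) sum(r[i]) - n1 * (n1 + 1) / 2, numeric(1))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

## Exact two-sided signed-rank p-value by enumeration of all sign patterns.
signrankEnumP <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  vs <- signs %*% r
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}
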