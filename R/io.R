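## ---------------------------------------------------------------------------
## Readers/writers: TIFF stacks with plain-text YAML sidecars, CSV tables.
## 32-bit float TIFF round-trips values in [0, 1] only, so images are stored
## scaled; scale/offset live in the sidecar.
## ---------------------------------------------------------------------------

slotsToList <- function(obj) {
  sl <- methods::slotNames(class(obj))
  out <- lapply(sl, function(s) {
    v <- methods::slot(obj, s)
    if (is.null(v)) NULL else as.vector(v)
  })
  names(out) <- sl
  out
}

acqFromList <- function(x) {
  AcquisitionSpec(height_px = as.integer(x$height_px),
                  width_px = as.integer(x$width_px),
                  pixel_um = x$pixel_um, frame_ms = x$frame_ms,
                  n_frames = as.integer(x$n_frames),
                  onset_frame = as.integer(x$onset_frame))
}

stimFromList <- function(x) {
  if (is.null(x)) return(NULL)
  StimulusSpec(modality = x$modality, pulse_ms = x$pulse_ms,
               power_mw = x$power_mw, current_ua = x$current_ua,
               n_pulses = as.integer(x$n_pulses %||% 1L),
               rate_hz = x$rate_hz, site_px = as.numeric(x$site_px))
}

writeFrames <- function(frames3d, path) {
  pages <- lapply(seq_len(dim(frames3d)[1]), function(k) frames3d[k, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
}

readFrames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  arr
}

#' Write a trial stack as TIFF files with a YAML sidecar
#'
#' One multi-page 32-bit float TIFF per trial (`<name>_trialNNN.tif`, one
#' page per frame, values scaled to [0, 1]) plus `<name>.yaml` recording the
#' acquisition spec, stimulus, labels and the scale factor.
#'
#' @param stack a [TrialStack].
#' @param dir output directory (created if missing).
#' @param name file-name stem.
#' @return Invisibly, the sidecar path.
#' @export
writeTrialStack <- function(stack, dir, name) {
  stopifnot(is(stack, "TrialStack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(stack@data)
  if (scale <= 0) scale <- 1
  n_tr <- dim(stack@data)[1]
  for (tr in seq_len(n_tr))
    writeFrames(stack@data[tr, , , ] / scale,
                file.path(dir, sprintf("%s_trial%03d.tif", name, tr)))
  meta <- list(
    kind = "TrialStack", name = name, n_trials = n_tr, scale = scale,
    acq = slotsToList(stack@acq),
    stim = if (is.null(stack@stim)) NULL else slotsToList(stack@stim),
    session_id = stack@session_id, condition = stack@condition
  )
  side <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(meta, side, precision = 15L)
  invisible(side)
}

#' Read a trial stack written by [writeTrialStack()]
#'
#' @param dir directory holding the files.
#' @param name file-name stem.
#' @return A [TrialStack].
#' @export
readTrialStack <- function(dir, name) {
  meta <- yaml::read_yaml(file.path(dir, paste0(name, ".yaml")))
  acq <- acqFromList(meta$acq)
  arr <- array(0, c(meta$n_trials, acq@n_frames, acq@height_px, acq@width_px))
  for (tr in seq_len(meta$n_trials))
    arr[tr, , , ] <- readFrames(
      file.path(dir, sprintf("%s_trial%03d.tif", name, tr))) * meta$scale
  TrialStack(data = arr, acq = acq, stim = stimFromList(meta$stim),
             session_id = meta$session_id %||% "",
             condition = meta$condition %||% "")
}

#' Write a delta-f/f movie as TIFF + mask + YAML sidecar
#'
#' `<name>.tif` holds the movie (affinely scaled to [0, 1]; masked entries
#' stored as 0 and recorded in `<name>_mask.tif`, a 0/1 pixel-validity
#' image); the sidecar records the scale, offset, time axis, frame validity
#' and trial count.  The retained per-trial stacks are not serialized.
#'
#' @param movie a [DffMovie].
#' @param dir output directory.
#' @param name file-name stem.
#' @return Invisibly, the sidecar path.
#' @export
writeDffMovie <- function(movie, dir, name) {
  stopifnot(is(movie, "DffMovie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- movie@data
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  sc <- (v - rng[1]) / (rng[2] - rng[1])
  sc[is.na(sc)] <- 0
  writeFrames(sc, file.path(dir, paste0(name, ".tif")))
  tiff::writeTIFF(movie@valid_pixels * 1,
                  file.path(dir, paste0(name, "_mask.tif")),
                  bits.per.sample = 32L)
  meta <- list(
    kind = "DffMovie", name = name, offset = rng[1], scale = diff(rng),
    time_ms = movie@time_ms, valid_frames = movie@valid_frames,
    n_trials = movie@n_trials, acq = slotsToList(movie@acq),
    stim = if (is.null(movie@stim)) NULL else slotsToList(movie@stim),
    condition = movie@condition, session_id = movie@session_id
  )
  side <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(meta, side, precision = 15L)
  invisible(side)
}

#' Read a delta-f/f movie written by [writeDffMovie()]
#'
#' Masked frames/pixels are restored as `NA`.  The per-trial stacks are not
#' serialized, so the returned movie has a zero-length `trials` slot and
#' across-trial SEMs are not recomputable from it.
#'
#' @param dir directory holding the files.
#' @param name file-name stem.
#' @return A [DffMovie].
#' @export
readDffMovie <- function(dir, name) {
  meta <- yaml::read_yaml(file.path(dir, paste0(name, ".yaml")))
  acq <- acqFromList(meta$acq)
  arr <- readFrames(file.path(dir, paste0(name, ".tif"))) * meta$scale +
    meta$offset
  vp <- tiff::readTIFF(file.path(dir, paste0(name, "_mask.tif"))) > 0.5
  vf <- as.logical(meta$valid_frames)
  arr[!vf, , ] <- NA_real_
  for (k in which(vf)) arr[k, , ][!vp] <- NA_real_
  DffMovie(data = arr, time_ms = as.numeric(meta$time_ms),
           valid_frames = vf, valid_pixels = vp,
           n_trials = as.integer(meta$n_trials),
           trials = array(numeric(0), c(0, acq@n_frames, acq@height_px,
                                        acq@width_px)),
           acq = acq, stim = stimFromList(meta$stim),
           condition = meta$condition %||% "",
           session_id = meta$session_id %||% "")
}

#' Write time courses as tidy CSV
#'
#' @param tcs a time-course data frame or a list of them (rows are bound).
#' @param file output CSV path.
#' @return Invisibly, `file`.
#' @export
writeTimeCourses <- function(tcs, file) {
  if (is.data.frame(tcs)) tcs <- list(tcs)
  utils::write.csv(do.call(rbind, tcs), file, row.names = FALSE)
  invisible(file)
}

#' Write a space-time map as a CSV matrix
#'
#' Rows are rings (labelled by outer-edge distance), columns are frame times.
#'
#' @param map a [SpaceTimeMap].
#' @param file output CSV path.
#' @return Invisibly, `file`.
#' @export
writeSpaceTimeMap <- function(map, file) {
  m <- map@values
  df <- data.frame(distance_um = map@distance_um, m)
  names(df)[-1] <- paste0("t", map@time_ms)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a decay map as a CSV matrix
#'
#' Plain-text rows x cols matrix of decay times (ms); missing pixels (never
#' crossed, invalid, or non-positive peak) are empty cells.
#'
#' @param map a [DecayMap].
#' @param file output CSV path.
#' @return Invisibly, `file`.
#' @export
writeDecayMap <- function(map, file) {
  utils::write.table(map@times_ms, file, sep = ",", na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write/read a YFP image as TIFF + YAML sidecar
#'
#' @param img a [YFPImage].
#' @param dir directory.
#' @param name file-name stem.
#' @return Invisibly, the sidecar path (write) or a [YFPImage] (read).
#' @export
writeYfpImage <- function(img, dir, name) {
  stopifnot(is(img, "YFPImage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(img@data)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  tiff::writeTIFF((img@data - rng[1]) / diff(rng),
                  file.path(dir, paste0(name, ".tif")),
                  bits.per.sample = 32L)
  tiff::writeTIFF(img@mask * 1, file.path(dir, paste0(name, "_mask.tif")),
                  bits.per.sample = 32L)
  meta <- list(kind = "YFPImage", offset = rng[1], scale = diff(rng),
               normalized = img@normalized, animal = img@animal,
               group = img@group)
  side <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(meta, side, precision = 15L)
  invisible(side)
}

#' @rdname writeYfpImage
#' @export
readYfpImage <- function(dir, name) {
  meta <- yaml::read_yaml(file.path(dir, paste0(name, ".yaml")))
  dat <- tiff::readTIFF(file.path(dir, paste0(name, ".tif"))) * meta$scale +
    meta$offset
  msk <- tiff::readTIFF(file.path(dir, paste0(name, "_mask.tif"))) > 0.5
  YFPImage(data = dat, mask = msk, normalized = isTRUE(meta$normalized),
           animal = meta$animal %||% "", group = meta$group %||% "")
}
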