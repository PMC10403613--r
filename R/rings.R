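## ---------------------------------------------------------------------------
## Ring-ROI space-time analysis: annulus construction, space-time maps,
## summed activation, spatial profiles, distance-resolved time courses.
## ---------------------------------------------------------------------------

#' Elementary ring bands used for distance-resolved time courses
#'
#' Distance bands (um) of the three reported rings: ring1 0.15-0.35 mm,
#' ring2 0.7-0.9 mm, ring3 1.25-1.45 mm from the peak response.
#' @export
ringBands <- list(ring1 = c(150, 350), ring2 = c(700, 900),
                  ring3 = c(1250, 1450))

#' Build the concentric ring set
#'
#' Partitions the image into concentric non-overlapping annuli around
#' `center_px`: ring k holds the pixels whose center-to-center distance d
#' (um) satisfies `(k-1)*step_um < d <= k*step_um`, up to `max_radius_um`.
#' With 50 um steps (one pixel) to a 2 mm radius this yields exactly 40
#' disjoint rings covering every pixel with `0 < d <= 2000` um; pixels beyond
#' the maximum radius (or outside the frame) belong to no ring.
#'
#' @param center_px ring center (row, col), typically the peak response.
#' @param acq an [AcquisitionSpec].
#' @param step_um ring width (um).
#' @param max_radius_um outermost radius (um).
#' @return A [RingSet].
#' @examples
#' rs <- buildRings(c(50, 50), AcquisitionSpec())
#' nRings(rs)
#' @export
buildRings <- function(center_px, acq, step_um = 50, max_radius_um = 2000) {
  stopifnot(is(acq, "AcquisitionSpec"))
  if (center_px[1] < 1 || center_px[1] > acq@height_px ||
      center_px[2] < 1 || center_px[2] > acq@width_px)
    stop("ring center lies outside the frame")
  if (step_um <= 0) stop("step_um must be > 0")
  if (abs(step_um / acq@pixel_um - round(step_um / acq@pixel_um)) > 1e-9)
    warning("step_um is not a multiple of the pixel pitch; ring widths are fractional pixels")
  n_rings <- as.integer(round(max_radius_um / step_um))
  d <- distanceGrid(acq@height_px, acq@width_px, center_px, acq@pixel_um)
  lab <- ceiling(d / step_um - 1e-9)
  lab[d <= 1e-9 | lab > n_rings] <- NA_real_
  RingSet(label = matrix(as.integer(lab), nrow(d), ncol(d)),
          center_px = as.numeric(center_px), step_um = step_um,
          n_rings = n_rings, distance_um = step_um * seq_len(n_rings),
          central_rings = 1:5, pixel_um = acq@pixel_um)
}

#' Ring-by-frame space-time map
#'
#' Mean delta-f/f per ring per frame (mask-aware: masked pixels are excluded
#' from ring means, and a ring left with no valid pixel carries `NA`), plus
#' the central-ring row.  The central value is the mean of the ring means of
#' rings 1-5 (`center = "rings1_5"`, the definition used for normalization;
#' chosen over a 150 um circle ROI, which is available as
#' `center = "circle150"`).
#'
#' @param movie a [DffMovie].
#' @param rings a [RingSet] built on the same geometry.
#' @param center central-ring definition, `"rings1_5"` or `"circle150"`.
#' @return A [SpaceTimeMap] (normalization `"raw"`).
#' @export
spaceTimeMap <- function(movie, rings,
                         center = c("rings1_5", "circle150")) {
  stopifnot(is(movie, "DffMovie"), is(rings, "RingSet"))
  center <- match.arg(center)
  if (!all(dim(rings@label) == dim(movie@valid_pixels)))
    stop("ring set and movie have mismatched geometry")
  nf <- dim(movie@data)[1]
  lab <- as.vector(rings@label)
  ok_px <- as.vector(movie@valid_pixels) & !is.na(lab)
  idx <- split(which(ok_px), lab[ok_px])
  values <- matrix(NA_real_, rings@n_rings, nf)
  for (k in seq_len(nf)) {
    if (!movie@valid_frames[k]) next
    v <- as.vector(movie@data[k, , ])
    for (r in names(idx)) {
      vv <- v[idx[[r]]]
      vv <- vv[!is.na(vv)]
      if (length(vv)) values[as.integer(r), k] <- mean(vv)
    }
  }
  ctr <- if (center == "rings1_5") {
    apply(values[rings@central_rings, , drop = FALSE], 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    })
  } else {
    disc <- distanceGrid(nrow(rings@label), ncol(rings@label),
                         rings@center_px, rings@pixel_um) <= 150 + 1e-9
    disc <- disc & movie@valid_pixels
    vapply(seq_len(nf), function(k) {
      if (!movie@valid_frames[k] || !any(disc)) return(NA_real_)
      mean(movie@data[k, , ][disc], na.rm = TRUE)
    }, numeric(1))
  }
  SpaceTimeMap(values = values, center = ctr, time_ms = movie@time_ms,
               distance_um = rings@distance_um,
               valid_frames = movie@valid_frames,
               normalization = "raw", condition = movie@condition,
               session_id = movie@session_id)
}

#' Normalize a space-time map to its central peak
#'
#' Divides every entry (and the central row) by the central-ring value at
#' t = 20 ms, which becomes exactly 1.  Enables comparison of
#' spatio-temporal spread across conditions irrespective of peak amplitude.
#'
#' @param map a [SpaceTimeMap].
#' @param t_ref_ms reference time (ms).
#' @return The normalized map (tag `"norm_to_center_t20"`).
#' @export
normalizeToCenter <- function(map, t_ref_ms = 20) {
  stopifnot(is(map, "SpaceTimeMap"))
  nrm <- map@center[frameAt(map@time_ms, t_ref_ms)]
  if (is.na(nrm) || nrm <= 0)
    stop("central value at the reference frame must be > 0")
  map@values <- map@values / nrm
  map@center <- map@center / nrm
  map@normalization <- "norm_to_center_t20"
  map
}

#' Summed activation over space and time
#'
#' Sum of the ring-mean values over all rings with outer edge `<= r_to_um`
#' and all valid frames with `t_from_ms <= t <= t_to_ms` (both ends
#' inclusive; with the defaults, 40 rings x 9 frames).  Works on raw or
#' normalized maps.
#'
#' @param map a [SpaceTimeMap].
#' @param t_from_ms,t_to_ms time window (ms).
#' @param r_to_um outermost ring edge included (um).
#' @return Scalar summed activation.
#' @export
summedActivation <- function(map, t_from_ms = 20, t_to_ms = 100,
                             r_to_um = 2000) {
  stopifnot(is(map, "SpaceTimeMap"))
  rs <- which(map@distance_um <= r_to_um + 1e-9)
  ks <- which(map@valid_frames & map@time_ms >= t_from_ms - 1e-9 &
                map@time_ms <= t_to_ms + 1e-9)
  if (length(rs) == 0L || length(ks) == 0L)
    stop("empty summation window")
  sum(map@values[rs, ks], na.rm = TRUE)
}

#' Spatial profile at a given time
#'
#' The map column at `t_ms` as a function of ring distance (outer edge, um);
#' the spatial cross-section of the response at the time of peak.
#'
#' @param map a [SpaceTimeMap].
#' @param t_ms requested time (ms); the frame must be valid.
#' @return Data frame with columns `distance_um` and `value`.
#' @export
spatialProfile <- function(map, t_ms = 20) {
  stopifnot(is(map, "SpaceTimeMap"))
  k <- frameAt(map@time_ms, t_ms)
  if (!map@valid_frames[k])
    stop(sprintf("frame at t = %g ms is invalid", t_ms))
  data.frame(distance_um = map@distance_um, value = map@values[, k])
}

#' Distance-band time course
#'
#' Mean over the elementary 50 um rings whose full extent lies within one of
#' the reported distance bands (ring1: 150-350 um, i.e. elementary rings 4-7;
#' ring2: 700-900 um; ring3: 1250-1450 um), per frame.
#'
#' @param map a [SpaceTimeMap].
#' @param band `"ring1"`, `"ring2"` or `"ring3"`.
#' @return A time-course data frame (`sem` is `NA`; band means pool ring
#'   means, not trials).
#' @export
ringTimeCourse <- function(map, band = c("ring1", "ring2", "ring3")) {
  stopifnot(is(map, "SpaceTimeMap"))
  band <- match.arg(band)
  lim <- ringBands[[band]]
  inner <- map@distance_um - diff(map@distance_um[1:2])
  rs <- which(inner >= lim[1] - 1e-9 & map@distance_um <= lim[2] + 1e-9)
  if (length(rs) == 0L) stop("band contains no rings")
  vals <- apply(map@values[rs, , drop = FALSE], 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  vals[!map@valid_frames] <- NA_real_
  data.frame(time_ms = map@time_ms, value = vals, sem = NA_real_,
             n_trials = NA_integer_, condition = map@condition,
             session_id = map@session_id,
             normalization = paste0(map@normalization, ":", band),
             stringsAsFactors = FALSE)
}

#' Rings composing a distance band
#'
#' @param map_or_rings a [SpaceTimeMap] or [RingSet].
#' @param band band name (see [ringBands]).
#' @return Integer indices of the elementary rings inside the band.
#' @export
bandRings <- function(map_or_rings, band = c("ring1", "ring2", "ring3")) {
  band <- match.arg(band)
  dist <- if (is(map_or_rings, "RingSet")) map_or_rings@distance_um
          else map_or_rings@distance_um
  lim <- ringBands[[band]]
  step <- diff(dist[1:2])
  which(dist - step >= lim[1] - 1e-9 & dist <= lim[2] + 1e-9)
}
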