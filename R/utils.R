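`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
## seed = NULL leaves the RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Matrix of center-to-center distances (um) of every pixel to `center_px`.
distanceGrid <- function(nrow_px, ncol_px, center_px, pixel_um) {
  dr <- (seq_len(nrow_px) - center_px[1])^2
  dc <- (seq_len(ncol_px) - center_px[2])^2
  pixel_um * sqrt(outer(dr, dc, "+"))
}

## NA-aware boxcar (moving-average) smoothing of a matrix with a w x w
## window; each output pixel is the mean of the non-NA window entries,
## NA where the window holds no data.  w must be odd; w = 1 is a no-op.
boxcarSmooth <- function(m, w = 3L) {
  stopifnot(w >= 1L, w %% 2L == 1L)
  if (w == 1L) return(m)
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc)
  n <- matrix(0L, nr, nc)
  for (dr in -h:h) {
    rsrc <- intersect(seq_len(nr), seq_len(nr) - dr)
    rdst <- rsrc + dr
    for (dc in -h:h) {
      csrc <- intersect(seq_len(nc), seq_len(nc) - dc)
      cdst <- csrc + dc
      v <- m[rsrc, csrc, drop = FALSE]
      ok <- !is.na(v)
      v[!ok] <- 0
      s[rdst, cdst] <- s[rdst, cdst] + v
      n[rdst, cdst] <- n[rdst, cdst] + ok
    }
  }
  out <- s / n
  out[n == 0L] <- NA_real_
  out
}

## Index of the frame whose time is t_ms (exact match within tolerance).
frameAt <- function(time_ms, t_ms, tol = 1e-6) {
  k <- which(abs(time_ms - t_ms) < tol)
  if (length(k) != 1L)
    stop(sprintf("no unique frame at t = %g ms", t_ms), call. = FALSE)
  k
}

## Standard error of the mean, NA-dropping; NA for n < 2.
semOf <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

## Logical membership matrix of a circular ROI (pixel-center distances, px).
circleMask <- function(nrow_px, ncol_px, center_px, radius_px) {
  dr <- (seq_len(nrow_px) - center_px[1])^2
  dc <- (seq_len(ncol_px) - center_px[2])^2
  outer(dr, dc, "+") <= radius_px^2 + 1e-9
}
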