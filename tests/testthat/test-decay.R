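# Movie in which every pixel follows the supplied t >= 20 ms samples
# (two baseline frames and the t = 0/10 ms frames prepended as zeros).
decayMovie <- function(samples, t0 = 20, frame_ms = 10) {
  vals <- c(rep(0, 2), rep(0, t0 / frame_ms), samples)
  acq <- tinyAcq(h = 4L, w = 4L, n_frames = length(vals), onset = 3L,
                 frame_ms = frame_ms)
  movieFromTimecourse(vals, acq)
}

test_that("threshold crossing uses linear interpolation between frames", {
  ## samples at t = 20..60 ms: [1, .8, .5, .2, .1] * peak, threshold 30%
  mv <- decayMovie(c(1, 0.8, 0.5, 0.2, 0.1) * 0.004)
  dm <- decayTimeMap(mv, 0.3)
  expect_equal(mapValues(dm)[1, 1], 40 + 10 * (0.5 - 0.3) / (0.5 - 0.2))
  expect_equal(mapValues(dm)[1, 1], 46 + 2 / 3, tolerance = 1e-12)
  ## high threshold crosses earlier on the same signal
  dm70 <- decayTimeMap(mv, 0.7)
  expect_equal(mapValues(dm70)[1, 1], 30 + 10 * (0.8 - 0.7) / (0.8 - 0.5))
})

test_that("never-crossed and non-positive-peak rules hold", {
  ## a signal flat at 0.25 of peak after the anchor crosses on the first
  ## inter-frame segment
  mv <- decayMovie(c(1, 0.25, 0.25, 0.25) * 0.004)
  expect_equal(mapValues(decayTimeMap(mv, 0.3))[1, 1],
               20 + 10 * (1 - 0.3) / (1 - 0.25))
  mv2 <- decayMovie(c(1, 2, 3, 4) * 0.004)   # rising: never below
  dm2 <- decayTimeMap(mv2, 0.3)
  expect_true(all(is.na(mapValues(dm2))))
  expect_identical(dm2@n_not_crossed, 16L)
  mv3 <- decayMovie(c(-1, -2, -3, -4) * 0.004)  # non-positive peak
  dm3 <- decayTimeMap(mv3, 0.3)
  expect_true(all(is.na(mapValues(dm3))))
  expect_identical(dm3@n_not_crossed, 0L)
  expect_error(decayTimeMap(mv, 1.2), "threshold_fraction")
})

test_that("piecewise-linear signals cross exactly; monotonicity and scale invariance hold", {
  set.seed(11)
  acq <- tinyAcq(h = 1L, w = 1L, n_frames = 12L, onset = 3L)
  for (i in 1:1000) {
    ## random decreasing-ish signal, positive peak at t = 20 ms (frame 5)
    peak <- runif(1, 0.5, 2)
    post <- c(peak, peak * sort(runif(7, -0.2, 1.1), decreasing = TRUE))
    vals <- c(0, 0, 0, 0.3 * peak, post)
    mv <- movieFromTimecourse(vals, acq)
    t30 <- mapValues(decayTimeMap(mv, 0.3))[1, 1]
    t70 <- mapValues(decayTimeMap(mv, 0.7))[1, 1]
    ## analytic crossing on the linear segments
    oracle <- function(thr_frac) {
      thr <- thr_frac * peak
      tt <- seq(20, 90, by = 10)
      if (post[1] < thr) return(20)
      for (j in 2:length(post)) {
        if (post[j] < thr)
          return(tt[j - 1] + 10 * (post[j - 1] - thr) / (post[j - 1] - post[j]))
      }
      NA_real_
    }
    expect_identical(is.na(t30), is.na(oracle(0.3)))
    if (!is.na(t30)) expect_equal(t30, oracle(0.3), tolerance = 1e-12)
    if (!is.na(t70)) expect_equal(t70, oracle(0.7), tolerance = 1e-12)
    ## decay to the lower threshold can never precede the higher one
    if (!is.na(t30) && !is.na(t70)) expect_gte(t30, t70)
    ## fractional thresholds make the map scale-invariant
    k <- runif(1, 0.1, 10)
    mvk <- movieFromTimecourse(vals * k, acq)
    t30k <- mapValues(decayTimeMap(mvk, 0.3))[1, 1]
    expect_equal(t30k, t30, tolerance = 1e-9)
  }
})

test_that("band distributions pool pixels and summarize as median +/- MAD", {
  acq <- AcquisitionSpec()
  rs <- buildRings(c(50, 50), acq)
  ## every pixel decays at exactly 20 ms: median 20, MAD 0 in both bands
  n <- 100
  dm <- DecayMap(times_ms = matrix(20, n, n), threshold_fraction = 0.3,
                 peak = matrix(1, n, n), valid = matrix(TRUE, n, n),
                 t_start_ms = 20, t_end_ms = 150, n_not_crossed = 0L)
  dd <- decayDistributions(dm, rs)
  expect_identical(dd$summary$median, c(20, 20))
  expect_identical(dd$summary$mad, c(0, 0))
  ## band sample sizes match the ring partition
  expect_identical(dd$summary$n[1], nrow(ringPixels(rs, 4:7)))
  ## hand-checked summaries
  expect_equal(unname(summarizeSample(c(20, 30, 40), "median_mad")),
               c(30, 10))
  expect_equal(unname(summarizeSample(c(20, 20, 20), "median_mad")),
               c(20, 0))
})

test_that("slow-component weight separates decay medians of the presets", {
  acq <- tinyAcq(h = 30L, w = 30L, n_frames = 16L, onset = 3L)
  meds <- vapply(c("short_exp", "long_exp"), function(nm) {
    p <- vsdPreset(nm, site_px = c(15, 15))
    art <- p$art; art@bleach_radius_um <- 0; art@bleach_depth <- 0
    art@noise_sd <- 0.2
    ses <- simulateSession(acq, p$stim, p$resp, art, 6, 4, seed = 21)
    mv <- preprocessSession(ses$stimulated, ses$blank, mask_bleach = FALSE)
    rs <- buildRings(c(15, 15), acq, max_radius_um = 500)
    dm <- decayTimeMap(mv, 0.3)
    sel <- !is.na(rs@label) & rs@label %in% 4:7
    stats::median(dm@times_ms[sel], na.rm = TRUE)
  }, numeric(1))
  expect_lt(meds[["short_exp"]], meds[["long_exp"]])
})

test_that("bi-exponential fitting recovers exact parameters from a clean curve", {
  tt <- seq(0, 300, by = 10)
  v <- ifelse(tt < 20, 0,
              0.004 * (0.55 * exp(-(tt - 20) / 18) +
                       0.45 * exp(-(tt - 20) / 100)))
  fit <- fitDecayTaus(tt, v)
  expect_equal(fit$tau_fast_ms, 18, tolerance = 1e-6)
  expect_equal(fit$tau_slow_ms, 100, tolerance = 1e-6)
  expect_equal(fit$w_fast, 0.55, tolerance = 1e-6)
})
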