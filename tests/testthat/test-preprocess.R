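stackFromFrames <- function(frames, acq, stim = NULL) {
  ## frames: list (one per trial) of frames x rows x cols arrays
  arr <- array(0, c(length(frames), dim(frames[[1]])))
  for (tr in seq_along(frames)) arr[tr, , , ] <- frames[[tr]]
  TrialStack(data = arr, acq = acq, stim = stim, session_id = "t",
             condition = "test")
}

test_that("frame-zero division matches hand-computed delta-f/f", {
  acq <- tinyAcq(h = 2L, w = 2L, n_frames = 4L, onset = 3L)
  base <- array(1000, c(4, 2, 2))
  ## constant trial: all zeros
  st <- stackFromFrames(list(base), acq)
  expect_equal(frameZeroDivide(st)[1, , , ], array(0, c(4, 2, 2)))
  ## baseline 1000, one response frame at 1004 -> 0.004
  f <- base; f[4, , ] <- 1004
  expect_equal(frameZeroDivide(stackFromFrames(list(f), acq))[1, 4, 1, 1],
               0.004)
  ## baselines 999 and 1001 average to 1000; response frame 1000 -> 0
  f2 <- base; f2[1, , ] <- 999; f2[2, , ] <- 1001; f2[4, , ] <- 1000
  expect_equal(frameZeroDivide(stackFromFrames(list(f2), acq))[1, 4, 1, 1], 0)
  ## non-positive baseline names the offending pixel
  f3 <- base; f3[1:2, 2, 1] <- 0
  expect_error(frameZeroDivide(stackFromFrames(list(f3), acq)),
               "pixel \\(2, 1\\)")
})

test_that("blank subtraction removes shared components exactly", {
  dims <- c(2, 5, 3, 3)
  stim <- array(rnorm(prod(dims)), dims)
  ## blank mean identical to a stimulated trial -> that trial becomes zero
  blank <- array(0, c(3, 5, 3, 3))
  for (tr in 1:3) blank[tr, , , ] <- stim[1, , , ]
  out <- blankSubtract(stim, blank)
  expect_equal(out[1, , , ], array(0, dims[-1]))
  ## a shared linear drift is removed to machine precision
  drift <- array(rep(seq(0, 4e-3, length.out = 5), each = 1), c(5, 3, 3))
  sig <- array(rnorm(prod(dims[-1])), dims[-1])
  s2 <- array(0, dims); b2 <- array(0, c(4, 5, 3, 3))
  for (tr in 1:2) s2[tr, , , ] <- sig + drift
  for (tr in 1:4) b2[tr, , , ] <- drift
  out2 <- blankSubtract(s2, b2)
  for (tr in 1:2) expect_lt(max(abs(out2[tr, , , ] - sig)), 1e-12)
  ## zero blank mean -> identity
  expect_equal(blankSubtract(stim, array(0, c(2, 5, 3, 3))), stim)
  expect_error(blankSubtract(stim, array(0, c(2, 4, 3, 3))), "mismatched")
})

test_that("trial averaging is the arithmetic mean and keeps per-trial data", {
  acq <- tinyAcq(h = 3L, w = 3L, n_frames = 5L, onset = 2L)
  one <- array(rnorm(5 * 3 * 3), c(5, 3, 3))
  d1 <- array(0, c(1, 5, 3, 3)); d1[1, , , ] <- one
  mv1 <- averageTrials(d1, acq)
  expect_equal(movieData(mv1), one)
  ## antisymmetric trials cancel
  d2 <- array(0, c(2, 5, 3, 3)); d2[1, , , ] <- one; d2[2, , , ] <- -one
  expect_equal(movieData(averageTrials(d2, acq)), array(0, c(5, 3, 3)))
  ## constants 1, 2, 3 average to 2
  d3 <- array(0, c(3, 5, 3, 3))
  for (tr in 1:3) d3[tr, , , ] <- tr
  mv3 <- averageTrials(d3, acq)
  expect_equal(movieData(mv3), array(2, c(5, 3, 3)))
  expect_identical(nTrials(mv3), 3L)
  expect_identical(trialData(mv3), d3)
})

test_that("stimulation-frame masking hits exactly t = 0 and 10 ms for opto and is idempotent", {
  acq <- tinyAcq()
  mv <- movieFromTimecourse(rep(1, acq@n_frames), acq)
  op <- maskStimulationFrames(mv, modality = "opto")
  expect_identical(which(!validFrames(op)),
                   which(frameTimes(acq) %in% c(0, 10)))
  expect_true(all(is.na(movieData(op)[!validFrames(op), , ])))
  expect_identical(validFrames(maskStimulationFrames(op, "opto")),
                   validFrames(op))
  ## ICMS: nothing removed
  expect_identical(validFrames(maskStimulationFrames(mv, "icms")),
                   rep(TRUE, acq@n_frames))
})

test_that("bleach masking invalidates exactly the constructed spot", {
  acq <- tinyAcq()
  site <- c(10, 10)
  arr <- array(0.001, c(acq@n_frames, 20, 20))
  spot <- distanceGridOracle(acq, site) <= 100 + 1e-9   # 5 pixels
  k_spot <- sum(spot)
  for (kk in which(frameTimes(acq) >= 20 & frameTimes(acq) <= 40))
    arr[kk, , ][spot] <- -0.01
  ## one deep-negative pixel far outside the search radius must survive
  arr[, 20, 20] <- -0.05
  mv <- movieFromArray(arr, acq,
                       stim = StimulusSpec(modality = "opto", pulse_ms = 10,
                                           site_px = site))
  out <- maskBleachedPixels(mv, search_radius_um = 300)
  expect_identical(sum(!validPixels(out)), k_spot)
  expect_true(all(!validPixels(out)[spot]))
  expect_true(validPixels(out)[20, 20])
  ## nothing below threshold -> mask untouched
  mv2 <- movieFromArray(array(0.001, c(acq@n_frames, 20, 20)), acq,
                        stim = mv@stim)
  expect_true(all(validPixels(maskBleachedPixels(mv2))))
})

test_that("masked entries never propagate into downstream means", {
  acq <- tinyAcq()
  p <- vsdPreset("long_exp", site_px = c(10, 10))
  ses <- simulateSession(acq, p$stim, p$resp, p$art, 3, 2, seed = 3)
  mv <- preprocessSession(ses$stimulated, ses$blank, search_radius_um = 300)
  ctr <- findPeakCenter(mv)
  tc <- extractTimeCourse(mv, ctr)
  rs <- buildRings(ctr, acq, max_radius_um = 500)
  stm <- spaceTimeMap(mv, rs)
  ## poison every masked pixel and frame with an absurd value
  poisoned <- mv
  for (kk in seq_len(dim(poisoned@data)[1])) {
    fr <- poisoned@data[kk, , ]
    fr[!validPixels(mv)] <- 1e6
    if (!validFrames(mv)[kk]) fr[] <- 1e6
    poisoned@data[kk, , ] <- fr
  }
  poisoned@data[is.na(mv@data) & !is.na(poisoned@data)] <- 1e6
  ## re-apply masks as NA markers the way the pipeline guarantees
  poisoned@data[!validFrames(mv), , ] <- NA_real_
  for (kk in which(validFrames(mv)))
    poisoned@data[kk, , ][!validPixels(mv)] <- NA_real_
  tc2 <- extractTimeCourse(poisoned, ctr)
  expect_equal(tc2$value, tc$value)
  expect_equal(mapValues(spaceTimeMap(poisoned, rs)), mapValues(stm))
})

test_that("the full chain recovers the generator's field on noise-free data", {
  acq <- tinyAcq()
  p <- vsdPreset("long_exp", site_px = c(10, 10))
  ses <- simulateSession(acq, p$stim, p$resp, cleanArt(), 2, 2, seed = 9)
  mv <- preprocessSession(ses$stimulated, ses$blank, mask_bleach = FALSE)
  R <- ses$truth@dff
  ok <- validFrames(mv)
  expect_lt(max(abs(movieData(mv)[ok, , ] - R[ok, , ])), 1e-10)
  ## linear operations commute: averaging before subtracting the blank mean
  ## equals the per-trial order used by the pipeline
  dff_s <- frameZeroDivide(ses$stimulated)
  dff_b <- frameZeroDivide(ses$blank)
  avg_first <- colMeans(dff_s) - colMeans(dff_b)
  sub_first <- colMeans(blankSubtract(dff_s, dff_b))
  expect_equal(avg_first, sub_first, tolerance = 1e-14)
})

test_that("preprocessSession requires blank trials", {
  acq <- tinyAcq()
  p <- vsdPreset("short_exp", site_px = c(10, 10))
  ses <- simulateSession(acq, p$stim, p$resp, p$art, 2, 2, seed = 1)
  expect_error(preprocessSession(ses$stimulated, NULL), "blank")
})
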