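test_that("identical seeds give bitwise-identical sessions, different seeds differ", {
  acq <- tinyAcq()
  p <- vsdPreset("short_exp", site_px = c(10, 10))
  s1 <- simulateSession(acq, p$stim, p$resp, p$art, 3, 2, seed = 5)
  s2 <- simulateSession(acq, p$stim, p$resp, p$art, 3, 2, seed = 5)
  s3 <- simulateSession(acq, p$stim, p$resp, p$art, 3, 2, seed = 6)
  expect_identical(trialData(s1$stimulated), trialData(s2$stimulated))
  expect_identical(trialData(s1$blank), trialData(s2$blank))
  expect_false(identical(trialData(s1$stimulated), trialData(s3$stimulated)))
})

test_that("zero amplitude with artifacts and noise off gives identical stimulated and blank stacks", {
  acq <- tinyAcq()
  p <- vsdPreset("long_exp", site_px = c(10, 10))
  resp <- p$resp; resp@amplitude <- 0
  ses <- simulateSession(acq, p$stim, resp, cleanArt(), 2, 2, seed = 1)
  expect_identical(trialData(ses$stimulated)[1, , , ],
                   trialData(ses$blank)[1, , , ])
})

test_that("closed-form peak and decay values are recovered at the center pixel", {
  acq <- tinyAcq(n_frames = 15L)
  site <- c(10, 10)
  stim <- StimulusSpec(modality = "opto", pulse_ms = 10, site_px = site)
  resp <- ResponseModel(amplitude = 0.004, sigma0_um = 300, speed_um_ms = 1,
                        w_fast = 1, w_slow = 0, tau_fast_ms = 10,
                        tau_slow_ms = 50, t_peak_ms = 20,
                        pulse_gamma = 0.5, pulse_ref_ms = 10)
  ses <- simulateSession(acq, stim, resp, cleanArt(), 2, 2, seed = 1)
  mv <- preprocessSession(ses$stimulated, ses$blank, mask_bleach = FALSE)
  ctc <- vapply(seq_along(mv@time_ms), function(k)
    movieData(mv)[k, site[1], site[2]], numeric(1))
  ## peak of the recovered center-pixel signal equals the model amplitude
  expect_equal(max(ctc, na.rm = TRUE), 0.004, tolerance = 1e-12)
  expect_equal(ctc[which(mv@time_ms == 20)], 0.004, tolerance = 1e-12)
  ## pure fast decay with tau = 10 ms: value at t = 30 is peak * exp(-1)
  expect_equal(ctc[which(mv@time_ms == 30)], 0.004 * exp(-1),
               tolerance = 1e-12)
})

test_that("with noise off the raw stimulated-minus-blank difference is exactly F0 * R", {
  acq <- tinyAcq()
  p <- vsdPreset("long_exp", site_px = c(10, 10))
  art <- cleanArt()
  art@drift_slope <- -2e-4; art@heartbeat_amp <- 1e-3  # shared components on
  ses <- simulateSession(acq, p$stim, p$resp, art, 1, 1, seed = 1)
  R <- ses$truth@dff
  diff_raw <- trialData(ses$stimulated)[1, , , ] - trialData(ses$blank)[1, , , ]
  ## the shared drift/heartbeat cancel exactly; the residual is F0 * R, with
  ## F0 given by the documented baseline profile (1000 a.u., mild vignetting)
  d <- distanceGridOracle(acq, c((acq@height_px + 1) / 2,
                                 (acq@width_px + 1) / 2)) / acq@pixel_um
  F0 <- 1000 * (1 - 0.05 * (d / max(d))^2)
  expected <- array(0, dim(R))
  for (k in seq_len(dim(R)[1])) expected[k, , ] <- F0 * R[k, , ]
  expect_lt(max(abs(diff_raw - expected)), 1e-9)
  ## and after the full preprocess chain the recovered dff is R up to the
  ## baseline-mean factor of the shared components (small)
  mv <- preprocessSession(ses$stimulated, ses$blank, mask_frames = FALSE,
                          mask_bleach = FALSE)
  expect_lt(max(abs(movieData(mv) - R)), 1e-5)
})

test_that("peak dff is non-decreasing in pulse duration", {
  acq <- tinyAcq()
  for (nm in c("short_exp", "long_exp")) {
    peaks <- vapply(c(2, 5, 10), function(pms) {
      p <- vsdPreset(nm, pulse_ms = pms, site_px = c(10, 10))
      max(responseField(acq, p$stim, p$resp))
    }, numeric(1))
    expect_true(all(diff(peaks) > 0))
  }
})

test_that("presets preserve the amplitude, slow-weight and extent orderings", {
  ps <- lapply(c("short_exp", "long_exp", "icms"), vsdPreset)
  amp <- vapply(ps, function(p) p$resp@amplitude, numeric(1))
  wsl <- vapply(ps, function(p) p$resp@w_slow, numeric(1))
  sig <- vapply(ps, function(p) p$resp@sigma0_um, numeric(1))
  expect_true(all(diff(amp) > 0))
  expect_true(wsl[1] < wsl[2] && wsl[2] <= wsl[3])
  expect_true(all(diff(sig) > 0))
  ## weight normalization holds in every preset
  for (p in ps) expect_equal(p$resp@w_fast + p$resp@w_slow, 1)
  ## electrical stimulation has no optical artifacts
  icms <- ps[[3]]
  expect_identical(icms$art@laser_gain, 0)
  expect_identical(icms$art@bleach_depth, 0)
})

test_that("generator rejects invalid inputs", {
  acq <- tinyAcq()
  p <- vsdPreset("short_exp", site_px = c(200, 10))
  expect_error(simulateSession(acq, p$stim, p$resp, p$art, 2, 2, seed = 1),
               "outside the frame")
  p2 <- vsdPreset("short_exp", site_px = c(10, 10))
  expect_error(simulateSession(acq, p2$stim, p2$resp, p2$art, 0, 2, seed = 1),
               ">= 1")
  expect_error(ResponseModel(w_fast = 0.5, w_slow = 0.6), "w_fast")
  expect_error(ArtifactModel(bleach_depth = 0.1), "bleach_depth")
})

test_that("synthetic YFP images behave as constructed", {
  acq <- tinyAcq()
  ## flat zero-level image: no pixel crosses the 2-SD threshold
  img0 <- simulateYfpImage(acq, c(10, 10), extent_um = 100, level = 0,
                           background_sd = 0, seed = 1)
  expect_error(normalizeYfp(img0), "constant")
  ## a known patch on near-zero background is counted exactly
  img <- simulateYfpImage(acq, c(10, 10), extent_um = 100, level = 1,
                          background_sd = 1e-4, seed = 2)
  k <- sum(distanceGridOracle(acq, c(10, 10)) <= 100 + 1e-9)
  expect_identical(countExpressingPixels(normalizeYfp(img)), k)
  ## determinism
  imgA <- simulateYfpImage(acq, c(10, 10), 100, 0.5, 0.05, seed = 3)
  imgB <- simulateYfpImage(acq, c(10, 10), 100, 0.5, 0.05, seed = 3)
  expect_identical(imgA@data, imgB@data)
  expect_error(simulateYfpImage(acq, c(10, 10), extent_um = 1e5, level = 1),
               "larger than the frame")
})
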