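test_that("default ring set is 40 disjoint annuli covering everything within 2 mm", {
  acq <- AcquisitionSpec()
  rs <- buildRings(c(50, 50), acq)
  expect_identical(nRings(rs), 40L)
  ## exhaustive check against an independent distance computation
  d <- distanceGridOracle(acq, c(50, 50))
  expected <- matrix(NA_integer_, 100, 100)
  for (r in 1:100) for (cc in 1:100) {
    dd <- d[r, cc]
    if (dd > 0 && dd <= 2000) expected[r, cc] <- as.integer(ceiling(dd / 50 - 1e-9))
  }
  expect_identical(rs@label, expected)
  ## partition: sizes add up, no pixel in two rings (labels are single-valued
  ## by construction; verify coverage count)
  sizes <- tabulate(rs@label[!is.na(rs@label)], 40)
  expect_identical(sum(sizes), sum(d > 0 & d <= 2000))
  expect_true(all(sizes > 0))
})

test_that("ring 1 is the four edge-adjacent neighbors of the center", {
  rs <- buildRings(c(50, 50), AcquisitionSpec())
  px <- ringPixels(rs, 1)
  expect_identical(nrow(px), 4L)
  got <- px[order(px[, 1], px[, 2]), , drop = FALSE]
  dimnames(got) <- NULL
  expect_identical(got,
                   matrix(c(49L, 50L, 50L, 49L, 50L, 51L, 51L, 50L),
                          ncol = 2, byrow = TRUE))
  ## the center pixel itself (d = 0) belongs to no ring
  expect_true(is.na(rs@label[50, 50]))
})

test_that("space-time map equals a naive per-pixel loop on a small movie", {
  acq <- tinyAcq()
  set.seed(7)
  arr <- array(rnorm(acq@n_frames * 400), c(acq@n_frames, 20, 20))
  mv <- movieFromArray(arr, acq)
  rs <- buildRings(c(10, 10), acq, max_radius_um = 500)
  stm <- spaceTimeMap(mv, rs)
  d <- distanceGridOracle(acq, c(10, 10))
  for (k in seq_len(nRings(rs))) {
    inring <- d > (k - 1) * 50 & d <= k * 50
    for (fr in seq_len(acq@n_frames))
      expect_equal(mapValues(stm)[k, fr], mean(arr[fr, , ][inring]))
  }
  ## central row is the mean of the ring means 1-5
  expect_equal(stm@center,
               colMeans(mapValues(stm)[1:5, , drop = FALSE]))
})

test_that("constant movies give flat maps and forced normalization", {
  acq <- tinyAcq()
  mv <- movieFromTimecourse(rep(0.5, acq@n_frames), acq)
  rs <- buildRings(c(10, 10), acq, max_radius_um = 400)
  stm <- spaceTimeMap(mv, rs)
  expect_true(all(mapValues(stm) == 0.5))
  nm <- normalizeToCenter(stm)
  expect_true(all(mapValues(nm) == 1))
  expect_identical(nm@center[frameAtOracle(nm@time_ms, 20)], 1)
  expect_identical(nm@normalization, "norm_to_center_t20")
})

test_that("ring means of a centered Gaussian decrease with distance and match the closed form", {
  acq <- AcquisitionSpec()
  sig <- 450
  g <- exp(-distanceGridOracle(acq, c(50, 50))^2 / (2 * sig^2))
  arr <- array(0, c(acq@n_frames, 100, 100))
  for (k in seq_len(acq@n_frames)) arr[k, , ] <- g
  mv <- movieFromArray(arr, acq)
  rs <- buildRings(c(50, 50), acq)
  stm <- spaceTimeMap(mv, rs)
  prof <- spatialProfile(stm, t_ms = 20)
  expect_true(all(diff(prof$value) < 0))
  ## closed-form oracle: per-ring mean of the analytic Gaussian
  d <- distanceGridOracle(acq, c(50, 50))
  for (k in c(1, 5, 10, 20, 40)) {
    inring <- d > (k - 1) * 50 & d <= k * 50
    oracle <- mean(exp(-d[inring]^2 / (2 * sig^2)))
    expect_lt(abs(prof$value[k] - oracle) / oracle, 0.02)
  }
  ## normalized profile does not exceed 1 beyond the center
  nprof <- spatialProfile(normalizeToCenter(stm), t_ms = 20)
  expect_true(all(nprof$value[-(1:5)] <= 1))
})

test_that("summed activation counts the documented window and is linear", {
  acq <- AcquisitionSpec()
  mv <- movieFromTimecourse(rep(1, acq@n_frames), acq)
  rs <- buildRings(c(50, 50), acq)
  stm <- spaceTimeMap(mv, rs)
  ## 40 rings x 9 frames in t = [20, 100] at 10 ms sampling
  expect_identical(summedActivation(stm), 360)
  expect_identical(summedActivation(spaceTimeMap(
    movieFromTimecourse(rep(0, acq@n_frames), acq), rs)), 0)
  mv2 <- movieFromTimecourse(rep(2, acq@n_frames), acq)
  expect_identical(summedActivation(spaceTimeMap(mv2, rs)), 720)
  ## scale invariance of the normalized map
  expect_equal(summedActivation(normalizeToCenter(spaceTimeMap(mv2, rs))),
               summedActivation(normalizeToCenter(stm)))
  expect_error(summedActivation(stm, t_from_ms = 500, t_to_ms = 600), "empty")
})

test_that("distance bands map onto the right elementary rings", {
  rs <- buildRings(c(50, 50), AcquisitionSpec())
  expect_identical(bandRings(rs, "ring1"), 4:7)     # 150-350 um
  expect_identical(bandRings(rs, "ring2"), 15:18)   # 700-900 um
  expect_identical(bandRings(rs, "ring3"), 26:29)   # 1250-1450 um
  ## constant map -> constant band TC; remote band weaker than central band
  acq <- AcquisitionSpec()
  mv <- movieFromTimecourse(rep(0.2, acq@n_frames), acq)
  stm <- spaceTimeMap(mv, rs)
  expect_true(all(ringTimeCourse(stm, "ring2")$value == 0.2))
  sig <- 450
  g <- exp(-distanceGridOracle(acq, c(50, 50))^2 / (2 * sig^2))
  arr <- array(0, c(acq@n_frames, 100, 100))
  for (k in seq_len(acq@n_frames)) arr[k, , ] <- g
  gm <- spaceTimeMap(movieFromArray(arr, acq), rs)
  expect_lt(tcValueAt(ringTimeCourse(gm, "ring3"), 20),
            tcValueAt(ringTimeCourse(gm, "ring1"), 20))
  expect_error(ringTimeCourse(stm, "ring9"))
})
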