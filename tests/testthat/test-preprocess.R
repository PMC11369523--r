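test_that("trimming removes one second from each end and re-zeroes time", {
  rec <- make_recording(2001, fs = 100, seed = 1)     # exactly 20 s
  tr <- trimRecording(rec, 1)
  expect_equal(recordingDuration(tr), 18)
  expect_equal(tr@t[1], 0)
  expect_identical(trimRecording(rec, 0), rec)
  short <- make_recording(150, fs = 100, seed = 2)    # 1.5 s
  expect_error(trimRecording(short, 1), "too short")
})

test_that("duration gate discards strictly-below-minimum recordings", {
  mk <- function(secs) make_recording(secs * 100 + 1, fs = 100, seed = 3)
  expect_true(gateMinDuration(mk(18))$accepted)
  g <- gateMinDuration(make_recording(991, fs = 100, seed = 3))  # 9.9 s
  expect_false(g$accepted)
  expect_match(g$reason, "below")
  expect_true(gateMinDuration(mk(10))$accepted)      # exactly 10 s stays
})

test_that("resampling is the identity on already-uniform input", {
  rec <- make_recording(1000, fs = 100, jitter = 0, seed = 4)
  uni <- resampleUniform(rec, 100)
  expect_equal(nrow(uni@accel), 1000)
  expect_lt(max(abs(uni@accel - rec@accel)), 1e-9)
  expect_lt(max(abs(uni@gyro - rec@gyro)), 1e-9)
})

test_that("resampling recovers an analytic tone from jittered samples", {
  withr::with_seed(11, {
    n <- 1800
    t <- seq(0, by = 0.01, length.out = n) +
      c(0, runif(n - 1, -0.003, 0.003))
    t <- sort(t)
    sig <- sin(2 * pi * 1 * t)
    rec <- IMURecording(t, cbind(sig, 0 * t, 0 * t + 9.81),
                        matrix(0, n, 3))
    uni <- resampleUniform(rec, 100)
    grid <- sampleTimes(uni) + t[1]
    err <- uni@accel[, 1] - sin(2 * pi * grid)
    expect_lt(sqrt(mean(err^2)), 0.01)   # < 1% of unit amplitude
  })
})

test_that("two-sample input resamples to a linear ramp", {
  rec <- IMURecording(c(0, 1), matrix(c(0, 1), 2, 3), matrix(0, 2, 3))
  uni <- resampleUniform(rec, 100)
  expect_equal(nrow(uni@accel), 101)
  expect_equal(uni@accel[, 1], seq(0, 1, length.out = 101))
})

test_that("resampled length follows floor(T*fs)+1", {
  for (n in c(500, 777, 1999)) {
    rec <- make_recording(n, fs = 100, seed = n)
    dur <- rec@t[n] - rec@t[1]
    expect_equal(nrow(resampleUniform(rec, 100)@accel),
                 floor(dur * 100) + 1)
  }
})

test_that("band-pass rejects DC, passes in-band tones, kills near-Nyquist", {
  n <- 6000; t <- seq_len(n) / 100
  # constant offset is rejected by the 0.1 Hz high-pass edge (mean of the
  # central region, clear of the filter transients)
  uni <- uniform_from_accel(ax = rep(5, n))
  filt <- bandpassFilter(uni)
  core <- filt@accel[2000:4000, 1]
  expect_lt(abs(mean(core)), 1e-2)
  # 5 Hz unit tone passes within 5%
  uni <- uniform_from_accel(ax = sin(2 * pi * 5 * t))
  filt <- bandpassFilter(uni)
  amp <- max(abs(filt@accel[2000:4000, 1]))
  expect_lt(abs(amp - 1), 0.05)
  # 48 Hz tone attenuated by >= 20 dB
  uni <- uniform_from_accel(ax = sin(2 * pi * 48 * t))
  filt <- bandpassFilter(uni)
  amp <- sqrt(mean(filt@accel[2000:4000, 1]^2)) / sqrt(0.5)
  expect_lt(20 * log10(amp), -20)
  # length preserved; invalid designs refused
  expect_equal(nrow(filt@accel), n)
  expect_error(bandpassFilter(uni, high = 50), "Nyquist")
})

test_that("in-band tone power is preserved through resampling", {
  withr::with_seed(12, {
    n <- 2000
    t <- sort(seq(0, by = 0.01, length.out = n) +
                c(0, runif(n - 1, -0.002, 0.002)))
    sig <- sin(2 * pi * 3 * t)
    rec <- IMURecording(t, cbind(sig, 0 * t, 0 * t + 9.81),
                        matrix(0, n, 3))
    uni <- resampleUniform(rec, 100)
    expect_lt(abs(mean(uni@accel[, 1]^2) / mean(sig^2) - 1), 0.02)
  })
})

test_that("calibration is affine per axis and estimable from a static epoch", {
  rec <- make_recording(800, seed = 6)
  uni <- resampleUniform(rec, 100)
  expect_equal(calibrateRecording(uni, CalibrationParams()), uni)

  # gravity referencing: static |a| of 9.91 gains down to 9.81
  withr::with_seed(13, {
    n <- 1000
    static <- uniform_from_accel(ax = rnorm(n, 0, 1e-4),
                                 ay = rnorm(n, 0, 1e-4),
                                 az = rnorm(n, 9.91, 1e-4))
    params <- estimateCalibration(static, g = 9.81)
    cal <- calibrateRecording(static, params)
    expect_equal(mean(cal@accel[, 3]), 9.81, tolerance = 1e-6)
  })

  # offset contract: zero-mean channel offset by 0.2 shifts mean by -0.2*gain
  p <- CalibrationParams(gyroGain = c(1.5, 1, 1), gyroOffset = c(0.2, 0, 0))
  z <- uniform_from_accel(az = rep(9.81, 500))
  cal <- calibrateRecording(z, p)
  expect_equal(mean(cal@gyro[, 1]), -0.2 * 1.5, tolerance = 1e-12)
  expect_error(CalibrationParams(accelGain = c(-1, 1, 1)), "positive")
})

test_that("the full conditioning chain gates, filters and reports reasons", {
  rec <- make_recording(2001, seed = 8)
  out <- preprocessTrial(rec)
  expect_true(out$accepted)
  expect_equal(recordingDuration(out$filtered), recordingDuration(out$unfiltered))
  # gravity is still present in the unfiltered stream, absent after filtering
  expect_gt(mean(out$unfiltered@accel[, 3]), 9)
  expect_lt(abs(mean(out$filtered@accel[, 3])), 0.5)
  short <- make_recording(900, seed = 9)              # < 10 s post-trim
  out <- preprocessTrial(short)
  expect_false(out$accepted)
})
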