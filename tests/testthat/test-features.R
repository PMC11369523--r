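geom <- TaskGeometry()   # inner 0.5, ball 0.05 -> in-circle threshold 0.45

test_that("time-in-circle applies the strict threshold convention", {
  expect_equal(pctTimeInCircle(traj_at_r(rep(0, 100)), geom), 100)
  expect_equal(pctTimeInCircle(traj_at_r(rep(0.44, 100)), geom), 100)
  expect_equal(pctTimeInCircle(traj_at_r(rep(0.46, 100)), geom), 0)
  expect_equal(pctTimeInCircle(traj_at_r(rep(c(0, 0.9), 50)), geom), 50)
  expect_error(pctTimeInCircle(traj_at_r(numeric(0)), geom), "empty")
})

test_that("time-in-circle is invariant under rotation about the center", {
  withr::with_seed(31, {
    r <- runif(300); a <- runif(300, 0, 2 * pi)
    t <- seq_len(300) / 100
    base <- BallTrajectory(t, r * cos(a), r * sin(a))
    for (phi in c(0.7, 2.1)) {
      rot <- BallTrajectory(t, r * cos(a + phi), r * sin(a + phi))
      expect_equal(pctTimeInCircle(rot, geom), pctTimeInCircle(base, geom))
    }
  })
})

test_that("perfect score means 100% of samples inside the inner circle", {
  expect_true(perfectScore(traj_at_r(rep(0, 50)), geom))
  expect_false(perfectScore(traj_at_r(c(rep(0, 49), 0.6)), geom))
  # a tablet left flat on the table scores perfectly
  t <- seq(0, 20, by = 0.01)
  flat <- simulateBall(TiltSeries(t, 0 * t, 0 * t), geom, PhysicsParams())
  expect_true(perfectScore(normalizeDisplacement(flat, geom), geom))
})

test_that("radial symmetry sums first differences of the resultant", {
  tr <- traj_at_r(c(0, 0.2, 0.1))
  expect_equal(as.numeric(radialSymmetry(tr, "literal")), 0.1)
  expect_equal(as.numeric(radialSymmetry(tr, "absolute")), 0.3)
  expect_equal(attr(radialSymmetry(tr), "mode"), "absolute")
  expect_equal(as.numeric(radialSymmetry(traj_at_r(rep(0.3, 10)))), 0)
  # literal mode telescopes to r_end - r_start on any trajectory
  withr::with_seed(32, {
    r <- runif(200)
    expect_equal(as.numeric(radialSymmetry(traj_at_r(r), "literal")),
                 r[200] - r[1])
  })
  expect_error(radialSymmetry(traj_at_r(0.1)), "2 samples")
})

test_that("5-s epochs partition the test with the half-epoch trailing rule", {
  # 18 s at 100 Hz: epochs 5/5/5/3 (trailing 3 s kept)
  r <- c(rep(0, 500), rep(0, 500), rep(0.9, 500), rep(c(0, 0.9), 150))
  tr <- traj_at_r(r)
  ep <- epochTimeInCircle(tr, geom)
  expect_length(ep$epochs, 4)
  expect_equal(ep$epochs[1:3], c(100, 100, 0))
  expect_equal(ep$epochs[4], 50, tolerance = 0.01)

  ep2 <- list(mean = mean(c(100, 50)), sd = sd(c(100, 50)),
              fd = mean(diff(c(100, 50))))
  got <- epochTimeInCircle(traj_at_r(c(rep(0, 500), rep(c(0, 0.9), 250))),
                           geom)
  expect_equal(got$mean, 75)
  expect_equal(got$sd, ep2$sd, tolerance = 1e-12)   # ~35.36
  expect_equal(got$first_diff, -50)

  flat <- epochTimeInCircle(traj_at_r(rep(0, 2000)), geom)
  expect_equal(c(flat$mean, flat$sd, flat$first_diff), c(100, 0, 0))

  # a single epoch yields undefined spread statistics
  one <- epochTimeInCircle(traj_at_r(rep(0, 400)), geom)
  expect_true(is.na(one$sd) && is.na(one$first_diff))
})

test_that("spectral summaries locate tones and grade spectral flatness", {
  t <- seq(0, 30, by = 0.01)
  sp <- psdSpectralFeatures(sin(2 * pi * 2 * t), 100)
  expect_equal(sp$median_freq, 2, tolerance = 0.2)
  expect_lte(sp$sef95, 3)
  expect_lt(sp$spec_entropy, 0.3)

  withr::with_seed(33, {
    spw <- psdSpectralFeatures(rnorm(4096), 100)
    expect_gt(spw$spec_entropy, 0.9)
  })

  expect_true(is.na(psdSpectralFeatures(rep(0, 1000), 100)$median_freq))
  expect_true(is.na(psdSpectralFeatures(rnorm(100), 100)$median_freq))
})

test_that("sef95 never falls below the median frequency", {
  withr::with_seed(34, {
    for (k in 1:20) {
      x <- as.numeric(arima.sim(list(ar = runif(1, -0.6, 0.9)), 1024))
      sp <- psdSpectralFeatures(x, 100)
      expect_gte(sp$sef95, sp$median_freq)
    }
  })
})

test_that("sway measures match the closed form for a circle", {
  T <- 10; n <- 4000
  t <- seq(0, T, length.out = n)
  tr <- BallTrajectory(t, cos(2 * pi * t / T), sin(2 * pi * t / T))
  sw <- swayMetricsBall(tr)
  expect_equal(sw$sway_length[["mean"]], 2 * pi, tolerance = 0.01)
  expect_equal(sw$sway_velocity[["mean"]], 2 * pi / T, tolerance = 0.01)
  expect_equal(sw$sway_area, pi / T, tolerance = 0.01)
  expect_equal(sw$mean_sway_dist[["mean"]], 1, tolerance = 0.01)
  expect_equal(sw$mean_sway_freq[["mean"]], 1 / T, tolerance = 0.01)

  still <- swayMetricsBall(traj_at_r(rep(0.4, 100)))
  expect_equal(still$sway_length[["mean"]], 0)
  expect_equal(still$sway_area, 0)
  expect_equal(still$mean_sway_dist[["mean"]], 0)
})

test_that("sway measures scale with their homogeneity degrees", {
  withr::with_seed(35, {
    t <- seq_len(500) / 100
    tr1 <- BallTrajectory(t, cumsum(rnorm(500, 0, 0.01)),
                          cumsum(rnorm(500, 0, 0.01)))
    tr2 <- BallTrajectory(t, 2 * tr1@x, 2 * tr1@y)
    s1 <- swayMetricsBall(tr1); s2 <- swayMetricsBall(tr2)
    expect_equal(s2$mean_sway_dist, 2 * s1$mean_sway_dist)
    expect_equal(s2$resultant_sway_dist, 2 * s1$resultant_sway_dist)
    expect_equal(s2$sway_length, 2 * s1$sway_length)
    expect_equal(s2$sway_velocity, 2 * s1$sway_velocity)
    expect_equal(s2$sway_area, 4 * s1$sway_area)
    expect_equal(s2$mean_sway_freq, s1$mean_sway_freq)  # scale free
  })
})

test_that("IMU features match analytic fixtures", {
  n <- 3000; t <- seq_len(n) / 100
  rec <- uniform_from_accel(ax = sin(2 * pi * 1.5 * t), n = n)
  f <- imuFeatures(rec)
  expect_equal(f$rms_accel_x, 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(f$rms_accel_y, 0)
  expect_equal(f$rms_accel, f$rms_accel_x)    # magnitude of a single axis

  withr::with_seed(36, {
    sig <- 0.1
    rec2 <- uniform_from_accel(ax = rnorm(4096, 0, sig),
                               az = rnorm(4096, 0, sig), n = 4096)
    f2 <- imuFeatures(rec2)
    expect_equal(f2$ellipse95_area_accel, pi * 5.991 * sig^2,
                 tolerance = 0.1 * pi * 5.991 * sig^2)
  })

  z <- imuFeatures(uniform_from_accel(n = 600))
  expect_equal(z$rms_accel, 0)
  expect_true(is.na(z$median_freq_accel))
  expect_true(is.na(z$sway_jerk_accel))
})

test_that("RMS features are invariant under channel sign flips", {
  rec <- resampleUniform(make_recording(1200, seed = 37), 100)
  f1 <- imuFeatures(rec)
  rec2 <- UniformRecording(fs = rec@fs, accel = -rec@accel,
                           gyro = -rec@gyro)
  f2 <- imuFeatures(rec2)
  for (nm in c("rms_accel", "rms_accel_x", "rms_gyro", "rms_gyro_y",
               "ellipse95_area_accel", "sway_path_accel_x"))
    expect_equal(f2[[nm]], f1[[nm]])
})

test_that("every documented feature maps to exactly one output field", {
  ball_names <- c(
    "pct_time_in_circle", "radial_symmetry",
    "epoch_pct_mean", "epoch_pct_sd", "epoch_pct_first_diff",
    paste0("median_freq_", c("mean", "x", "y")),
    paste0("sef95_", c("mean", "x", "y")),
    "sway_area",
    paste0("mean_sway_freq_", c("mean", "x", "y")),
    paste0("mean_sway_dist_", c("mean", "x", "y")),
    paste0("resultant_sway_dist_", c("mean", "x", "y")),
    paste0("sway_length_", c("mean", "x", "y")),
    paste0("sway_velocity_", c("mean", "x", "y")))
  imu_names <- c(
    "rms_accel", "rms_accel_x", "rms_accel_y", "rms_accel_z",
    "rms_gyro", "rms_gyro_x", "rms_gyro_y",
    "median_freq_accel", "sef_accel", "spec_entropy_accel",
    "median_freq_gyro", "sef_gyro", "spec_entropy_gyro",
    "sway_path_accel_x", "sway_path_accel_z",
    "sway_area_accel", "sway_jerk_accel", "ellipse95_area_accel")
  tr <- traj_at_r(abs(0.3 * sin(seq_len(2000) / 50)))
  bf <- ballFeatures(tr, geom)
  expect_setequal(names(bf), c(ball_names, "perfect_score"))
  rec <- resampleUniform(make_recording(1200, seed = 38), 100)
  expect_setequal(names(imuFeatures(rec)), imu_names)
})

test_that("counting oracle: per-sample enumeration equals the implementation", {
  withr::with_seed(39, {
    for (k in 1:100) {
      n <- sample(20:200, 1)
      tr <- BallTrajectory(seq_len(n) / 100, runif(n, -1, 1),
                           runif(n, -1, 1))
      thr <- geom@innerRatio * geom@outerRadius - geom@ballRadius
      naive <- 0L
      for (i in seq_len(n))
        if (sqrt(tr@x[i]^2 + tr@y[i]^2) < thr) naive <- naive + 1L
      expect_identical(pctTimeInCircle(tr, geom), 100 * naive / n)
    }
  })
})
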