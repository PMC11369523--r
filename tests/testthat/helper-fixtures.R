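# Shared fixture builders: everything is generated in code at test time.

# Plausible six-channel recording: gravity on az plus small structured
# motion, strictly increasing (optionally jittered) timestamps.
make_recording <- function(n = 2000, fs = 100, condition = "single",
                           jitter = 0, seed = NULL) {
  gen <- function() {
    t <- seq(0, by = 1 / fs, length.out = n)
    if (jitter > 0) {
      t <- t + c(0, pmin(pmax(rnorm(n - 1, 0, jitter), -0.4 / fs),
                         0.4 / fs))
    }
    roll <- 0.03 * sin(2 * pi * 0.4 * t)
    pitch <- 0.02 * cos(2 * pi * 0.3 * t)
    acc <- cbind(-9.81 * sin(pitch) + rnorm(n, 0, 0.01),
                 9.81 * sin(roll) * cos(pitch) + rnorm(n, 0, 0.01),
                 9.81 * cos(roll) * cos(pitch) + rnorm(n, 0, 0.01))
    gyr <- cbind(c(0, diff(roll)) * fs * 180 / pi + rnorm(n, 0, 0.05),
                 c(0, diff(pitch)) * fs * 180 / pi + rnorm(n, 0, 0.05),
                 rnorm(n, 0, 0.05))
    IMURecording(t, acc, gyr, condition = condition)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

make_session <- function(id = "P1", seed = NULL, with_ball = FALSE) {
  gen <- function() {
    s <- make_recording(600, condition = "single")
    d <- make_recording(800, condition = "dual")
    sb <- db <- NULL
    if (with_ball) {
      sb <- data.frame(t = s@t, x = 0.1 * sin(s@t), y = 0.1 * cos(s@t))
      db <- data.frame(t = d@t, x = 0.2 * sin(d@t), y = 0.1 * cos(d@t))
    }
    Session(id, single = s, dual = d, singleBall = sb, dualBall = db)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Trajectory at given resultant displacements (placed along +x).
traj_at_r <- function(r, fs = 100) {
  n <- length(r)
  BallTrajectory(seq(0, by = 1 / fs, length.out = n), r, rep(0, n))
}

make_metadata <- function(n = 6, seed = 42) {
  withr::with_seed(seed, data.frame(
    participant_id = sprintf("P%d", seq_len(n)),
    age = sample(60:85, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    cohort = rep_len(c("healthy", "MCI", "ADRD"), n),
    mmse_total = sample(20:30, n, replace = TRUE),
    ravlt_total = sample(10:60, n, replace = TRUE),
    ravlt_long_delay = sample(0:14, n, replace = TRUE),
    faq_total = sample(0:20, n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# Uniform recording with chosen accel channels (gyro zero).
uniform_from_accel <- function(ax = NULL, ay = NULL, az = NULL, fs = 100,
                               n = NULL) {
  n <- if (is.null(n)) max(lengths(list(ax, ay, az))) else n
  z <- rep(0, n)
  acc <- cbind(if (is.null(ax)) z else ax,
               if (is.null(ay)) z else ay,
               if (is.null(az)) z else az)
  UniformRecording(fs = fs, accel = acc, gyro = matrix(0, n, 3))
}
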