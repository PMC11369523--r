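# Synthetic cohort generator: a delayed PD controller "participant"
# balances the virtual ball in closed loop; tablet IMU channels are
# synthesized from the applied tilt (gravity projection + sensor noise on
# the accelerometer, tilt increments + noise on the gyroscope). Dual-task
# trials add Poisson control interruptions (attention captured by the
# concurrent cognitive task). Cognitive scores are generated from a shared
# latent impairment factor so that score-label consistency and the modest
# inter-score correlations the analyses assume are present.

#' Simulate one ball-balancing trial
#'
#' Closed loop at `fs` Hz: the controller observes the ball state with a
#' sensorimotor delay, commands tilt through proportional-derivative
#' feedback with a first-order motor lag and per-step tilt jitter, and the
#' tilt drives the Newtonian ball model. Under the dual condition, Poisson
#' interruptions freeze the commanded tilt for `interruptionLen` seconds.
#' Returns both the synthesized IMU stream and the ground-truth ball
#' trajectory.
#'
#' @param params a [ControllerParams-class].
#' @param condition `"single"` (20 s) or `"dual"` (45 s).
#' @param duration trial length in seconds (protocol default by
#'   condition).
#' @param geom a [TaskGeometry-class].
#' @param phys a [PhysicsParams-class].
#' @param fs simulation / sampling rate, Hz.
#' @param accel_noise_sd,gyro_noise_sd IMU sensor noise SDs (m/s^2,
#'   deg/s); defaults are typical consumer-tablet MEMS figures.
#' @param ts_jitter_sd SD of timestamp jitter (s) emulating uneven tablet
#'   sampling; 0 gives an exactly uniform grid.
#' @param seed optional RNG seed (deterministic trial given seed).
#' @return List with `rec` ([IMURecording-class]), `ball`
#'   ([BallTrajectory-class], `source = "recorded"`), `tilt`
#'   ([TiltSeries-class], the applied tilt), and `saturated_frac` (the
#'   fraction of the trial spent pinned at the outer boundary; a warning
#'   is raised above 0.9, indicating an unstable gain combination).
#' @export
simulateTrial <- function(params, condition = "single",
                          duration = if (condition == "dual") 45 else 20,
                          geom = TaskGeometry(), phys = PhysicsParams(),
                          fs = 100, accel_noise_sd = 0.02,
                          gyro_noise_sd = 0.1, ts_jitter_sd = 1e-4,
                          seed = NULL) {
  run <- function() {
    n <- as.integer(round(duration * fs)) + 1L
    dt0 <- 1 / fs
    t <- seq(0, by = dt0, length.out = n)
    if (ts_jitter_sd > 0) {
      j <- pmin(pmax(rnorm(n, 0, ts_jitter_sd), -0.4 * dt0), 0.4 * dt0)
      j[1] <- 0
      t <- t + j
    }
    dts <- diff(t)
    # motor noise as slow postural drift: white noise through two first-
    # order poles (correlation ~0.7 s, stationary SD = motorNoiseSd), so
    # both the tilt and its derivative are band-limited and the ball,
    # whose dynamics low-pass fast tremor, is actually perturbed
    noise <- numeric(n)
    if (params@motorNoiseSd > 0) {
      tau_n <- 0.7
      rho <- exp(-dt0 / tau_n)
      gain <- (1 - rho) * sqrt(1 + rho^2) / (1 - rho^2)^1.5
      e <- rnorm(n, 0, params@motorNoiseSd / gain)
      x1 <- stats::filter(e, rho, method = "recursive")
      noise <- as.numeric(stats::filter((1 - rho) * x1, rho,
                                        method = "recursive"))
    }
    dual <- condition == "dual"
    interrupt_draw <- if (dual) runif(n) else NULL
    ilen_steps <- as.integer(round(params@interruptionLen * fs))
    delay_steps <- as.integer(round(params@reactionDelay * fs))
    kmax <- 0.26                              # command clamp, ~15 degrees
    R <- geom@outerRadius
    gscale <- phys@rollingFactor * phys@g * phys@screenScale
    c0 <- phys@damping
    g <- phys@g
    aw <- 0.02                                # in-app tilt-fusion weight
    anz <- matrix(rnorm(3 * n, 0, accel_noise_sd), n, 3)
    gnz <- matrix(rnorm(3 * n, 0, gyro_noise_sd), n, 3)
    x <- numeric(n); y <- numeric(n)
    applied_p <- numeric(n); applied_r <- numeric(n)
    ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
    gx <- numeric(n); gy <- numeric(n)
    est_p <- numeric(n); est_r <- numeric(n)
    vx <- 0; vy <- 0
    tilt_p <- 0; tilt_r <- 0
    cmd_p <- 0; cmd_r <- 0
    applied_p[1] <- noise[1]; applied_r[1] <- noise[1]
    # the app displays a ball driven by its own tilt estimate, computed
    # from the (noisy) sensors in real time; the participant closes the
    # loop around that displayed ball
    ax[1] <- -g * sin(applied_p[1]) + anz[1, 1]
    ay[1] <- g * sin(applied_r[1]) * cos(applied_p[1]) + anz[1, 2]
    az[1] <- g * cos(applied_r[1]) * cos(applied_p[1]) + anz[1, 3]
    est_r[1] <- atan2(ay[1], az[1])
    est_p[1] <- atan2(-ax[1], sqrt(ay[1]^2 + az[1]^2))
    interrupted_until <- 0L
    sat <- 0L
    uniform <- ts_jitter_sd == 0
    if (uniform) co <- .step_coeffs(c0, dt0)
    for (i in 2:n) {
      dti <- dts[i - 1]
      if (!uniform) co <- .step_coeffs(c0, dti)
      # controller update (delayed observation of the displayed ball)
      jdx <- min(i - delay_steps, i - 1)
      if (dual && i > interrupted_until && !is.null(interrupt_draw) &&
          interrupt_draw[i] < params@dtInterruptionRate * dt0)
        interrupted_until <- i + ilen_steps
      if (i > interrupted_until && jdx >= 2) {
        ox <- x[jdx]; oy <- y[jdx]
        ovx <- (x[jdx] - x[jdx - 1]) / dts[jdx - 1]
        ovy <- (y[jdx] - y[jdx - 1]) / dts[jdx - 1]
        cmd_p <- max(-kmax, min(kmax, -(params@kp * ox + params@kd * ovx)))
        cmd_r <- max(-kmax, min(kmax, -(params@kp * oy + params@kd * ovy)))
      }
      lag <- dti / params@motorLag
      if (lag > 1) lag <- 1
      tilt_p <- tilt_p + (cmd_p - tilt_p) * lag
      tilt_r <- tilt_r + (cmd_r - tilt_r) * lag
      applied_p[i] <- tilt_p + noise[i]
      applied_r[i] <- tilt_r + noise[i]
      # sensor synthesis: gravity projection + noise on the accelerometer,
      # interval-average tilt rate + noise on the gyroscope
      ax[i] <- -g * sin(applied_p[i]) + anz[i, 1]
      ay[i] <- g * sin(applied_r[i]) * cos(applied_p[i]) + anz[i, 2]
      az[i] <- g * cos(applied_r[i]) * cos(applied_p[i]) + anz[i, 3]
      gx[i] <- (applied_r[i] - applied_r[i - 1]) / dti + gnz[i, 1] * pi / 180
      gy[i] <- (applied_p[i] - applied_p[i - 1]) / dti + gnz[i, 2] * pi / 180
      # in-app complementary tilt fusion on the noisy sensor stream
      accr <- atan2(ay[i], az[i])
      accp <- atan2(-ax[i], sqrt(ay[i]^2 + az[i]^2))
      est_r[i] <- (1 - aw) * (est_r[i - 1] + gx[i] * dti) + aw * accr
      est_p[i] <- (1 - aw) * (est_p[i - 1] + gy[i] * dti) + aw * accp
      # ball step driven by the displayed (estimate-driven) tilt,
      # trapezoid-averaged over the step
      Axi <- (gscale * sin(est_p[i - 1]) + gscale * sin(est_p[i])) / 2
      Ayi <- (gscale * sin(est_r[i - 1]) + gscale * sin(est_r[i])) / 2
      x[i] <- x[i - 1] + co$k1 * vx + co$k2 * Axi
      y[i] <- y[i - 1] + co$k1 * vy + co$k2 * Ayi
      vx <- co$ev * vx + co$k1 * Axi
      vy <- co$ev * vy + co$k1 * Ayi
      r <- sqrt(x[i]^2 + y[i]^2)
      if (r > R) {
        sat <- sat + 1L
        x[i] <- x[i] * R / r; y[i] <- y[i] * R / r
        nx <- x[i] / R; ny <- y[i] / R
        vn <- vx * nx + vy * ny
        if (vn > 0) { vx <- vx - vn * nx; vy <- vy - vn * ny }
      }
    }
    satfrac <- sat / n
    if (satfrac > 0.9)
      warning(sprintf(
        "unstable gain combination: ball saturated %.0f%% of trial",
        100 * satfrac))
    gx <- gx * 180 / pi
    gy <- gy * 180 / pi
    gz <- gnz[, 3]
    rec <- IMURecording(t, cbind(ax, ay, az), cbind(gx, gy, gz),
                        condition = condition, nominalDuration = duration)
    list(rec = rec,
         ball = BallTrajectory(t, x, y, source = "recorded"),
         tilt = TiltSeries(t, applied_r, applied_p),
         saturated_frac = satfrac)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.COHORT_DEFAULTS <- list(
  healthy = list(z_mean = 0, age_mean = 70.5,
                 noise = 0.06, delay = 0.18, irate = 0.5),
  MCI = list(z_mean = 1, age_mean = 73.5,
             noise = 0.075, delay = 0.22, irate = 0.7),
  ADRD = list(z_mean = 2, age_mean = 75.0,
              noise = 0.10, delay = 0.26, irate = 0.7))

#' Default synthetic cohort configuration
#'
#' Emulates the structure of the clinical validation sample: 374
#' cohort-labelled participants (132 healthy, 116 MCI, 126 ADRD) plus one
#' participant without a valid cohort status label; ages 60-85 (overall
#' mean ~73); 56% female. Cohort-conditional controller parameters and
#' score distributions are driven by a shared latent impairment factor z,
#' which induces score-label consistency and an MMSE / RAVLT-long-delay
#' correlation of roughly 0.6.
#'
#' @param n_per_cohort named counts for healthy / MCI / ADRD.
#' @param n_missing_label participants simulated (as MCI-like) but with
#'   cohort `"missing"`.
#' @param seed cohort RNG seed.
#' @return Config list understood by [simulateCohort()].
#' @export
defaultCohortConfig <- function(n_per_cohort = c(healthy = 132, MCI = 116,
                                                 ADRD = 126),
                                n_missing_label = 1, seed = 1) {
  list(n_per_cohort = n_per_cohort, n_missing_label = n_missing_label,
       age_sd = 5.5, female_ratio = 0.56, z_sd = 0.6,
       cohorts = .COHORT_DEFAULTS,
       kp = 0.4, kd = 0.25, motor_lag = 0.15, interruption_len = 0.8,
       accel_noise_sd = 0.02, gyro_noise_sd = 0.1, ts_jitter_sd = 1e-4,
       fs = 100, duration_single = 20, duration_dual = 45,
       geom = TaskGeometry(), phys = PhysicsParams(), seed = seed)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.draw_scores <- function(z, n) {
  # score-specific noise keeps the mixture-level MMSE / RAVLT-long-delay
  # correlation near the modest ~0.6 the instruments show in older adults
  data.frame(
    mmse_total = .clip(round(29 - 2.6 * z + rnorm(n, 0, 2.0)), 0, 30),
    ravlt_total = .clip(round(52 - 13 * z + rnorm(n, 0, 8)), 0, 75),
    ravlt_long_delay = .clip(round(9.5 - 3.9 * z + rnorm(n, 0, 2.6)),
                             0, 15),
    faq_total = .clip(round(-1 + 5.5 * z + rnorm(n, 0, 2.5)), 0, 30))
}

.participant_params <- function(config, cohort, z) {
  cp <- config$cohorts[[cohort]]
  dz <- z - cp$z_mean
  ControllerParams(
    kp = config$kp * exp(-0.08 * dz), kd = config$kd,
    reactionDelay = max(0.05, cp$delay + 0.03 * dz),
    motorNoiseSd = cp$noise * exp(0.35 * dz),
    dtInterruptionRate = cp$irate * exp(0.3 * dz),
    interruptionLen = config$interruption_len,
    motorLag = config$motor_lag)
}

#' Simulate a complete synthetic cohort
#'
#' Per participant: age and sex are sampled, cohort-conditional controller
#' parameters are jittered through the latent impairment factor, one
#' single-task and one dual-task trial are simulated, and cognitive scores
#' (MMSE, RAVLT total and long delay, FAQ) are drawn from
#' cohort-conditional distributions correlated with the controller
#' impairment. Deterministic given `config$seed`.
#'
#' @param config list from [defaultCohortConfig()] (possibly tuned by
#'   [calibrateCohort()]).
#' @return List with `sessions` (list of [Session-class]), `metadata`
#'   (data.frame in the [readMetadata()] layout), `ball` (per participant,
#'   list with the ground-truth `single`/`dual` [BallTrajectory-class]
#'   objects), and `manifest`.
#' @export
simulateCohort <- function(config = defaultCohortConfig()) {
  withr::with_seed(config$seed, {
    plan <- c(rep(names(config$n_per_cohort), config$n_per_cohort),
              rep("missing", config$n_missing_label))
    n <- length(plan)
    ids <- sprintf("P%04d", seq_len(n))
    sessions <- vector("list", n)
    ball <- vector("list", n)
    meta <- vector("list", n)
    n_sat <- 0L
    for (i in seq_len(n)) {
      cohort <- plan[i]
      sim_cohort <- if (cohort == "missing") "MCI" else cohort
      cp <- config$cohorts[[sim_cohort]]
      z <- rnorm(1, cp$z_mean, config$z_sd)
      age <- .clip(round(rnorm(1, cp$age_mean, config$age_sd)), 60, 85)
      sex <- if (runif(1) < config$female_ratio) "female" else "male"
      params <- .participant_params(config, sim_cohort, z)
      st <- simulateTrial(params, "single", config$duration_single,
                          config$geom, config$phys, config$fs,
                          config$accel_noise_sd, config$gyro_noise_sd,
                          config$ts_jitter_sd)
      dtt <- simulateTrial(params, "dual", config$duration_dual,
                           config$geom, config$phys, config$fs,
                           config$accel_noise_sd, config$gyro_noise_sd,
                           config$ts_jitter_sd)
      n_sat <- n_sat + (st$saturated_frac > 0.9) + (dtt$saturated_frac > 0.9)
      sessions[[i]] <- Session(ids[i], single = st$rec, dual = dtt$rec,
                               singleBall = trajectoryFrame(st$ball)[
                                 c("t", "x", "y")],
                               dualBall = trajectoryFrame(dtt$ball)[
                                 c("t", "x", "y")])
      ball[[i]] <- list(single = st$ball, dual = dtt$ball)
      sc <- .draw_scores(z, 1)
      meta[[i]] <- data.frame(participant_id = ids[i], age = age,
                              sex = sex, cohort = cohort, sc,
                              stringsAsFactors = FALSE)
    }
    metadata <- do.call(rbind, meta)
    list(sessions = sessions, metadata = metadata, ball = ball,
         manifest = list(n = n, counts = table(plan),
                         n_unstable_trials = n_sat, seed = config$seed))
  })
}

# pct-time-in-circle of one simulated trial through the analysis path
# (resample full stream, tilt estimation, ball model from center/rest).
.derived_pct <- function(rec, geom, phys, fs = 100) {
  uni <- resampleUniform(rec, fs)
  traj <- deriveBallTrajectory(uni, geom, phys)
  pctTimeInCircle(traj, geom)
}

.cohort_mean_pct <- function(config, cohort, condition, n_reps,
                             seeds = NULL) {
  cp <- config$cohorts[[cohort]]
  dur <- if (condition == "dual") config$duration_dual
         else config$duration_single
  one <- function(r) {
    z <- rnorm(1, cp$z_mean, config$z_sd)
    params <- .participant_params(config, cohort, z)
    tr <- simulateTrial(params, condition, dur, config$geom, config$phys,
                        config$fs, config$accel_noise_sd,
                        config$gyro_noise_sd, config$ts_jitter_sd)
    .derived_pct(tr$rec, config$geom, config$phys)
  }
  mean(vapply(seq_len(n_reps), function(r) {
    if (is.null(seeds)) one(r)
    else withr::with_seed(seeds[r], one(r))
  }, numeric(1)))
}

#' Calibrate the cohort simulator to target group means
#'
#' Tunes, per cohort, the controller motor-noise SD against the
#' single-task target and then the dual-task interruption rate against
#' the dual-task target, by grid search minimizing the squared distance
#' between simulated group mean percentage-time-in-circle (measured
#' through the package's own analysis path) and the targets. Default
#' targets are the group means reported for the clinical validation
#' cohort the simulator emulates.
#'
#' @param config config list from [defaultCohortConfig()].
#' @param targets list with numeric vectors `st` and `dt`, named by
#'   cohort (percent).
#' @param n_reps simulated trials per grid cell (default 10).
#' @param noise_grid,irate_grid search grids for the motor-noise SD (rad)
#'   and interruption rate (1/s).
#' @param seed RNG seed for the calibration simulations.
#' @return The tuned config; achieved group means and a reachability flag
#'   are stored in `$calibration`. A warning is raised when a target is
#'   unreachable within the grid (best-effort config returned).
#' @export
calibrateCohort <- function(config = defaultCohortConfig(),
                            targets = list(
                              st = c(healthy = 92.6, MCI = 87.5,
                                     ADRD = 77.5),
                              dt = c(healthy = 70.2, MCI = 63.7,
                                     ADRD = 63.9)),
                            n_reps = 10,
                            noise_grid = c(0.02, 0.035, 0.05, 0.065, 0.08,
                                           0.10, 0.125, 0.15),
                            irate_grid = c(0.1, 0.25, 0.45, 0.7, 1.0, 1.4,
                                           1.9, 2.5),
                            seed = 1) {
  achieved <- list(st = c(), dt = c())
  search_lever <- function(cohort, lever, grid, condition, target) {
    # dual-task trials are about twice as variable per trial; scale reps
    reps <- if (condition == "dual") 2L * n_reps else n_reps
    # common random numbers across grid cells: every candidate value sees
    # the same participant draws, so cell differences reflect the lever
    sel_seeds <- sample.int(.Machine$integer.max - 1L, reps)
    fin_seeds <- sample.int(.Machine$integer.max - 1L, 3L * reps)
    eval_at <- function(v, seeds) {
      cfg <- config
      cfg$cohorts[[cohort]][[lever]] <- v
      .cohort_mean_pct(cfg, cohort, condition, length(seeds), seeds)
    }
    means <- vapply(grid, eval_at, numeric(1), seeds = sel_seeds)
    # two rounds of midpoint bisection around the running best cell
    for (round in 1:2) {
      b <- which.min((means - target)^2)
      srt <- order(grid)
      pos <- match(grid[b], grid[srt])
      extra <- c(if (pos > 1) (grid[srt][pos - 1] + grid[b]) / 2,
                 if (pos < length(grid)) (grid[srt][pos + 1] + grid[b]) / 2)
      extra <- setdiff(extra, grid)
      if (!length(extra)) break
      em <- vapply(extra, eval_at, numeric(1), seeds = sel_seeds)
      grid <- c(grid, extra); means <- c(means, em)
    }
    b <- which.min((means - target)^2)
    # the winning cell's estimate is selection-biased toward the target;
    # re-evaluate the chosen setting on fresh draws for an honest mean
    list(value = grid[b], mean = eval_at(grid[b], fin_seeds))
  }
  withr::with_seed(seed, {
    for (cohort in names(config$cohorts)) {
      st <- search_lever(cohort, "noise", noise_grid, "single",
                         targets$st[[cohort]])
      config$cohorts[[cohort]]$noise <- st$value
      achieved$st[cohort] <- st$mean
      dt <- search_lever(cohort, "irate", irate_grid, "dual",
                         targets$dt[[cohort]])
      config$cohorts[[cohort]]$irate <- dt$value
      achieved$dt[cohort] <- dt$mean
    }
  })
  miss <- c(abs(achieved$st - unlist(targets$st)[names(achieved$st)]),
            abs(achieved$dt - unlist(targets$dt)[names(achieved$dt)]))
  reachable <- all(miss <= 5)
  if (!reachable)
    warning("calibration targets not all reachable within the grid; ",
            "best-effort config returned")
  config$calibration <- list(targets = targets, achieved = achieved,
                             n_reps = n_reps, reachable = reachable)
  config
}

#' Write simulated sessions and metadata to a directory
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; emits one session JSON per participant, a
#'   metadata CSV and a manifest JSON.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions)
    writeSession(s, file.path(dir, paste0(s@participantId, ".json")))
  writeMetadata(cohort$metadata, file.path(dir, "metadata.csv"))
  jsonlite::write_json(cohort$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
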