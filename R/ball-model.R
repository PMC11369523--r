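# Virtual-ball kinematics: tablet tilt from IMU, Newtonian ball dynamics,
# screen normalization. The IMU is treated as rigid-plane rotation: roll
# (about screen x) and pitch (about screen y) fully describe the plane.
#
# Gravity projection convention (pinned by tests and used by the
# simulator):
#   ax = -g sin(pitch)
#   ay =  g sin(roll) cos(pitch)
#   az =  g cos(roll) cos(pitch)
# which inverts as roll = atan2(ay, az), pitch = atan2(-ax, sqrt(ay^2+az^2)).

.acc_angles <- function(accel) {
  roll <- atan2(accel[, 2], accel[, 3])
  pitch <- atan2(-accel[, 1], sqrt(accel[, 2]^2 + accel[, 3]^2))
  cbind(roll, pitch)
}

#' Estimate tablet tilt from an unfiltered IMU stream
#'
#' Complementary fusion of gravity-referenced accelerometer angles with
#' integrated gyroscope rates: at each step the gyro-propagated estimate is
#' pulled toward the accelerometer angle with weight `accel_weight`
#' (default 0.02 per step at 100 Hz). Band-passed channels exclude DC, so
#' tilt must be estimated from the pre-filter stream.
#'
#' Near free fall (acceleration magnitude below `0.1 g` for more than
#' 0.5 s) the accelerometer carries no orientation information; a warning
#' is raised and the accelerometer term is down-weighted tenfold over those
#' samples.
#'
#' @param rec an unfiltered [UniformRecording-class] (gravity present).
#' @param accel_weight complementary-filter accelerometer weight per step.
#' @return A [TiltSeries-class] (roll/pitch in radians).
#' @export
estimateTilt <- function(rec, accel_weight = 0.02) {
  stopifnot(is(rec, "UniformRecording"))
  n <- nrow(rec@accel)
  if (n < 2) stop("need at least 2 samples")
  dt <- 1 / rec@fs
  ang <- .acc_angles(rec@accel)
  rate <- rec@gyro[, 1:2, drop = FALSE] * pi / 180   # roll, pitch rad/s
  amag <- sqrt(rowSums(rec@accel^2))
  freefall <- amag < 0.1 * 9.81
  w <- rep(accel_weight, n)
  if (any(freefall)) {
    runs <- rle(freefall)
    if (any(runs$lengths[runs$values] > 0.5 * rec@fs)) {
      warning("near free-fall epoch > 0.5 s; accelerometer term down-weighted")
    }
    w[freefall] <- accel_weight / 10
  }
  est <- matrix(0, n, 2)
  est[1, ] <- ang[1, ]
  if (all(w == w[1])) {
    # constant weight: the recursion est_i = (1-w)(est_{i-1} + rate_i dt)
    # + w ang_i is linear and vectorizes through stats::filter
    a <- 1 - w[1]
    for (j in 1:2) {
      u <- a * rate[-1, j] * dt + w[1] * ang[-1, j]
      est[-1, j] <- stats::filter(u, a, method = "recursive",
                                  init = est[1, j])
    }
  } else {
    for (i in 2:n)
      est[i, ] <- (1 - w[i]) * (est[i - 1, ] + rate[i, ] * dt) +
        w[i] * ang[i, ]
  }
  TiltSeries(sampleTimes(rec), est[, 1], est[, 2])
}

# Exact per-step update for v' = A - c v with A held constant over a step.
# Returns position increment and end velocity.
.step_coeffs <- function(c, dt) {
  if (c == 0) list(ev = 1, k1 = dt, k2 = dt^2 / 2)
  else {
    ev <- exp(-c * dt)
    list(ev = ev, k1 = (1 - ev) / c, k2 = (dt - (1 - ev) / c) / c)
  }
  # v_{i+1} = ev v_i + k1 A_i ; dx_i = k1 v_i + k2 A_i
}

#' Integrate the Newtonian virtual-ball model over a tilt series
#'
#' The ball obeys `x'' = rollingFactor * g * sin(pitch) - damping * x'`
#' (and the y analogue with roll): tilting the tablet toward +x rolls the
#' ball toward +x. The ball is not perturbed unless the tablet is moved.
#' Integration is exact per step for tilt held constant over each step
#' (linear ODE, exponential integrator), positions are mapped to screen
#' units by `screenScale`, and the trajectory is boundary-handled at the
#' outer circle (`clamp`: the ball rests on the rim with the outward
#' velocity component zeroed).
#'
#' @param tilt a [TiltSeries-class] on a uniform grid.
#' @param geom a [TaskGeometry-class].
#' @param phys a [PhysicsParams-class].
#' @param init list with `pos = c(x, y)` (screen units) and
#'   `vel = c(vx, vy)` (screen units/s); defaults to rest at center.
#' @return A [BallTrajectory-class] (`source = "derived"`, same length as
#'   the tilt series, screen units relative to `outerRadius`).
#' @export
simulateBall <- function(tilt, geom = TaskGeometry(), phys = PhysicsParams(),
                         init = list(pos = c(0, 0), vel = c(0, 0))) {
  stopifnot(is(tilt, "TiltSeries"))
  n <- length(tilt@t)
  if (n < 2) stop("tilt series too short")
  dts <- diff(tilt@t)
  if (max(abs(dts - dts[1])) > 1e-9 * max(dts[1], 1))
    stop("tilt series must be on a uniform grid")
  dt <- dts[1]
  c0 <- phys@damping
  co <- .step_coeffs(c0, dt)
  # drive accelerations in screen units/s^2 (scale absorbed up front);
  # trapezoid-averaged over each step for second-order accuracy on a
  # smoothly varying tilt
  Ax <- phys@rollingFactor * phys@g * sin(tilt@pitch) * phys@screenScale
  Ay <- phys@rollingFactor * phys@g * sin(tilt@roll) * phys@screenScale
  R <- geom@outerRadius

  integrate_free <- function(A, x0, v0) {
    Aeff <- (A[-n] + A[-1]) / 2
    # v_{i+1} = ev v_i + k1 Aeff_i  (linear recursion)
    vin <- co$k1 * Aeff
    v <- c(v0, stats::filter(vin, co$ev, method = "recursive", init = v0))
    x <- c(x0, x0 + cumsum(co$k1 * v[-n] + co$k2 * Aeff))
    list(x = x, v = v)
  }
  fx <- integrate_free(Ax, init$pos[1], init$vel[1])
  fy <- integrate_free(Ay, init$pos[2], init$vel[2])
  r2 <- fx$x^2 + fy$x^2
  if (all(r2 <= R^2)) {
    return(BallTrajectory(tilt@t, fx$x, fy$x, source = "derived"))
  }
  # boundary interaction: step-by-step with clamping
  x <- numeric(n); y <- numeric(n)
  x[1] <- init$pos[1]; y[1] <- init$pos[2]
  vx <- init$vel[1]; vy <- init$vel[2]
  for (i in 2:n) {
    Axi <- (Ax[i - 1] + Ax[i]) / 2
    Ayi <- (Ay[i - 1] + Ay[i]) / 2
    x[i] <- x[i - 1] + co$k1 * vx + co$k2 * Axi
    y[i] <- y[i - 1] + co$k1 * vy + co$k2 * Ayi
    vx <- co$ev * vx + co$k1 * Axi
    vy <- co$ev * vy + co$k1 * Ayi
    r <- sqrt(x[i]^2 + y[i]^2)
    if (r > R) {
      if (phys@boundary == "clamp") {
        x[i] <- x[i] * R / r; y[i] <- y[i] * R / r
        # zero the outward-normal velocity component
        nx <- x[i] / R; ny <- y[i] / R
        vn <- vx * nx + vy * ny
        if (vn > 0) { vx <- vx - vn * nx; vy <- vy - vn * ny }
      } else {                         # reflect
        x[i] <- x[i] * (2 * R / r - 1); y[i] <- y[i] * (2 * R / r - 1)
        nx <- x[i]; ny <- y[i]; nr <- sqrt(nx^2 + ny^2)
        if (nr > 0) { nx <- nx / nr; ny <- ny / nr }
        vn <- vx * nx + vy * ny
        vx <- vx - 2 * vn * nx; vy <- vy - 2 * vn * ny
      }
    }
  }
  BallTrajectory(tilt@t, x, y, source = "derived")
}

#' Normalize a trajectory to the outer-circle radius
#'
#' Divides coordinates by the outer radius so the outer edge maps to
#' resultant displacement 1 and the center to 0.
#'
#' @param traj a [BallTrajectory-class].
#' @param geom a [TaskGeometry-class].
#' @return Normalized [BallTrajectory-class].
#' @export
normalizeDisplacement <- function(traj, geom = TaskGeometry()) {
  BallTrajectory(traj@t, traj@x / geom@outerRadius,
                 traj@y / geom@outerRadius, source = traj@source)
}

#' Derive the normalized on-screen ball trajectory from an IMU stream
#'
#' Convenience wrapper: tilt estimation on the unfiltered stream, Newtonian
#' ball integration, screen normalization.
#'
#' @param rec an unfiltered [UniformRecording-class].
#' @param geom a [TaskGeometry-class].
#' @param phys a [PhysicsParams-class].
#' @param init initial ball state, as in [simulateBall()].
#' @param accel_weight complementary-filter weight, see [estimateTilt()].
#' @return A normalized [BallTrajectory-class].
#' @export
deriveBallTrajectory <- function(rec, geom = TaskGeometry(),
                                 phys = PhysicsParams(),
                                 init = list(pos = c(0, 0), vel = c(0, 0)),
                                 accel_weight = 0.02) {
  tilt <- estimateTilt(rec, accel_weight)
  normalizeDisplacement(simulateBall(tilt, geom, phys, init), geom)
}
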