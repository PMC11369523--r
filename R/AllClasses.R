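#' @import methods
#' @importFrom stats approx splinefun fft rnorm runif rbinom sd cor median
#'   quantile wilcox.test cor.test lm anova pnorm plogis qchisq var
#'   binomial glm.fit p.adjust complete.cases setNames aggregate
#' @importFrom utils read.csv write.csv head tail modifyList
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Six-axis inertial recording for one trial
#'
#' Holds timestamped triaxial accelerometer (m/s^2) and gyroscope (deg/s)
#' samples for a single ball-balancing trial, together with the task
#' condition and the nominal protocol duration (20 s single task, 45 s dual
#' task).
#'
#' @slot t numeric vector, seconds from trial start (strictly increasing).
#' @slot accel n x 3 matrix, columns ax/ay/az in m/s^2 (tablet frame).
#' @slot gyro n x 3 matrix, columns gx/gy/gz in deg/s (tablet frame).
#' @slot condition `"single"` or `"dual"`.
#' @slot nominalDuration protocol duration in seconds.
#' @slot deviceMeta free-form named list of device metadata strings.
#' @export
setClass("IMURecording",
  representation(t = "numeric", accel = "matrix", gyro = "matrix",
                 condition = "character", nominalDuration = "numeric",
                 deviceMeta = "list"),
  prototype(condition = "single", nominalDuration = 20, deviceMeta = list()))

setValidity("IMURecording", function(object) {
  n <- length(object@t)
  if (nrow(object@accel) != n || nrow(object@gyro) != n)
    return("accel/gyro must have one row per timestamp")
  if (ncol(object@accel) != 3L || ncol(object@gyro) != 3L)
    return("accel and gyro must have 3 columns")
  if (n && any(!is.finite(object@t))) return("timestamps must be finite")
  if (n && object@t[1] < 0) return("timestamps must be >= 0")
  if (n > 1 && any(diff(object@t) <= 0))
    return("timestamps must be strictly increasing")
  if (n && (any(!is.finite(object@accel)) || any(!is.finite(object@gyro))))
    return("all six channels must be finite")
  if (!object@condition %in% c("single", "dual"))
    return("condition must be 'single' or 'dual'")
  TRUE
})

#' Construct an IMURecording
#'
#' @param t numeric timestamps (s), strictly increasing.
#' @param accel,gyro n x 3 numeric matrices (m/s^2, deg/s).
#' @param condition `"single"` or `"dual"`.
#' @param nominalDuration nominal protocol duration (s); defaults to 20 for
#'   single-task and 45 for dual-task trials.
#' @param deviceMeta named list of device metadata.
#' @return An [IMURecording-class] object.
#' @export
IMURecording <- function(t, accel, gyro, condition = "single",
                         nominalDuration = NULL, deviceMeta = list()) {
  if (is.null(nominalDuration))
    nominalDuration <- if (condition == "dual") 45 else 20
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  colnames(accel) <- c("ax", "ay", "az"); colnames(gyro) <- c("gx", "gy", "gz")
  new("IMURecording", t = as.numeric(t), accel = accel, gyro = gyro,
      condition = condition, nominalDuration = nominalDuration,
      deviceMeta = deviceMeta)
}

#' Uniformly resampled recording
#'
#' An [IMURecording-class] brought onto a uniform time grid (default 100 Hz),
#' the representation on which filtering and spectral feature extraction
#' operate.
#'
#' @slot fs sampling rate in Hz.
#' @slot accel,gyro n x 3 channel matrices on the uniform grid.
#' @slot t0Offset seconds trimmed/shifted from the original trial start.
#' @slot condition `"single"` or `"dual"`.
#' @export
setClass("UniformRecording",
  representation(fs = "numeric", accel = "matrix", gyro = "matrix",
                 t0Offset = "numeric", condition = "character"),
  prototype(fs = 100, t0Offset = 0, condition = "single"))

setValidity("UniformRecording", function(object) {
  if (object@fs <= 0) return("fs must be positive")
  if (nrow(object@accel) != nrow(object@gyro))
    return("accel and gyro must have equal length")
  TRUE
})

#' @rdname UniformRecording-class
#' @param ... slot values passed to the class prototype.
#' @return A `UniformRecording` object.
#' @export
UniformRecording <- function(fs, accel, gyro, t0Offset = 0,
                             condition = "single") {
  new("UniformRecording", fs = fs, accel = as.matrix(accel),
      gyro = as.matrix(gyro), t0Offset = t0Offset, condition = condition)
}

#' One participant's session: single- and dual-task trials
#'
#' @slot participantId opaque participant identifier.
#' @slot single,dual the two trial recordings (either may be NULL).
#' @slot singleBall,dualBall optional app-recorded ball positions
#'   (data.frame with columns t, x, y in screen-normalized units).
#' @export
setClass("Session",
  representation(participantId = "character", single = "ANY", dual = "ANY",
                 singleBall = "data.frameOrNULL",
                 dualBall = "data.frameOrNULL"),
  prototype(single = NULL, dual = NULL, singleBall = NULL, dualBall = NULL))

setValidity("Session", function(object) {
  for (sl in c("single", "dual")) {
    r <- slot(object, sl)
    if (!is.null(r) && !is(r, "IMURecording"))
      return(sprintf("slot '%s' must be an IMURecording or NULL", sl))
  }
  if (is.null(object@single) && is.null(object@dual))
    return("session must contain at least one trial")
  TRUE
})

#' @rdname Session-class
#' @param ... slot values passed to the class prototype.
#' @return A `Session` object.
#' @export
Session <- function(participantId, single = NULL, dual = NULL,
                    singleBall = NULL, dualBall = NULL) {
  new("Session", participantId = as.character(participantId), single = single,
      dual = dual, singleBall = singleBall, dualBall = dualBall)
}

#' Tablet tilt time series
#'
#' Roll/pitch (radians) of the tablet plane on a uniform grid, estimated by
#' complementary fusion of gravity-referenced accelerometer angles and
#' integrated gyroscope rates.
#'
#' @slot t uniform time grid (s).
#' @slot roll,pitch tilt angles in radians (rotation about screen x / y).
#' @export
setClass("TiltSeries",
  representation(t = "numeric", roll = "numeric", pitch = "numeric"))

setValidity("TiltSeries", function(object) {
  if (length(object@roll) != length(object@t) ||
      length(object@pitch) != length(object@t))
    return("roll/pitch must match the time grid")
  if (any(abs(c(object@roll, object@pitch)) >= pi / 2))
    return("tilt angles must satisfy |angle| < pi/2")
  TRUE
})

#' @rdname TiltSeries-class
#' @param ... slot values passed to the class prototype.
#' @return A `TiltSeries` object.
#' @export
TiltSeries <- function(t, roll, pitch)
  new("TiltSeries", t = as.numeric(t), roll = as.numeric(roll),
      pitch = as.numeric(pitch))

#' Task geometry: target circles and ball size
#'
#' The scoring zones of the ball-balancing task: an outer circle of
#' normalized radius 1, an inner target circle sized as a ratio of the
#' outer, and the ball radius. The ball counts as "in the circle" when its
#' resultant displacement is strictly less than
#' `innerRatio * outerRadius - ballRadius`.
#'
#' @slot outerRadius normalized outer radius (1 by convention).
#' @slot innerRatio inner/outer radius ratio in (0, 1).
#' @slot ballRadius ball radius in normalized units.
#' @export
setClass("TaskGeometry",
  representation(outerRadius = "numeric", innerRatio = "numeric",
                 ballRadius = "numeric"),
  prototype(outerRadius = 1, innerRatio = 0.5, ballRadius = 0.05))

setValidity("TaskGeometry", function(object) {
  if (object@innerRatio <= 0 || object@innerRatio >= 1)
    return("innerRatio must lie in (0, 1)")
  if (object@ballRadius >= object@innerRatio * object@outerRadius)
    return("ballRadius must be smaller than the inner circle radius")
  TRUE
})

#' @rdname TaskGeometry-class
#' @param outerRadius,innerRatio,ballRadius see slots.
#' @return A `TaskGeometry` object.
#' @export
TaskGeometry <- function(outerRadius = 1, innerRatio = 0.5,
                         ballRadius = 0.05)
  new("TaskGeometry", outerRadius = outerRadius, innerRatio = innerRatio,
      ballRadius = ballRadius)

#' Newtonian parameters of the virtual-ball model
#'
#' The ball accelerates in proportion to the gravity component along the
#' tilted screen: `x'' = rollingFactor * g * sin(pitch) - damping * x'`
#' (and the y analogue with roll). Physical displacement (metres) is mapped
#' to normalized screen units by `screenScale`; the trajectory is
#' boundary-handled at the outer circle.
#'
#' @slot g gravitational acceleration, m/s^2.
#' @slot rollingFactor 1 for a point mass, 5/7 for a rolling solid sphere.
#' @slot damping viscous damping rate, 1/s.
#' @slot screenScale normalized screen units per metre.
#' @slot boundary `"clamp"` (ball rests on the rim) or `"reflect"`.
#' @export
setClass("PhysicsParams",
  representation(g = "numeric", rollingFactor = "numeric", damping = "numeric",
                 screenScale = "numeric", boundary = "character"),
  prototype(g = 9.81, rollingFactor = 1, damping = 0.05,
            screenScale = 0.585, boundary = "clamp"))

setValidity("PhysicsParams", function(object) {
  if (object@damping < 0) return("damping must be >= 0")
  if (object@screenScale <= 0) return("screenScale must be > 0")
  if (!object@boundary %in% c("clamp", "reflect"))
    return("boundary must be 'clamp' or 'reflect'")
  TRUE
})

#' @rdname PhysicsParams-class
#' @param g,rollingFactor,damping,screenScale,boundary see slots. The
#'   default `screenScale` is chosen so a sustained 5 degree tilt carries
#'   the ball from center to the outer edge in about 2 s.
#' @return A `PhysicsParams` object.
#' @export
PhysicsParams <- function(g = 9.81, rollingFactor = 1, damping = 0.05,
                          screenScale = 0.585, boundary = "clamp")
  new("PhysicsParams", g = g, rollingFactor = rollingFactor,
      damping = damping, screenScale = screenScale, boundary = boundary)

#' Virtual-ball trajectory on screen
#'
#' @slot t uniform time grid (s).
#' @slot x,y screen displacement (normalized units once
#'   [normalizeDisplacement()] has been applied; center = 0).
#' @slot source `"recorded"` (app log) or `"derived"` (kinematic model).
#' @export
setClass("BallTrajectory",
  representation(t = "numeric", x = "numeric", y = "numeric",
                 source = "character"),
  prototype(source = "derived"))

setValidity("BallTrajectory", function(object) {
  if (length(object@x) != length(object@t) ||
      length(object@y) != length(object@t))
    return("x/y must match the time grid")
  if (!object@source %in% c("recorded", "derived"))
    return("source must be 'recorded' or 'derived'")
  TRUE
})

#' @rdname BallTrajectory-class
#' @param ... slot values passed to the class prototype.
#' @return A `BallTrajectory` object.
#' @export
BallTrajectory <- function(t, x, y, source = "derived")
  new("BallTrajectory", t = as.numeric(t), x = as.numeric(x),
      y = as.numeric(y), source = source)

#' Per-axis affine calibration parameters
#'
#' Channels are corrected as `gain * (channel - offset)`, per axis.
#'
#' @slot accelGain,accelOffset length-3 numeric (unitless / m/s^2).
#' @slot gyroGain,gyroOffset length-3 numeric (unitless / deg/s).
#' @export
setClass("CalibrationParams",
  representation(accelGain = "numeric", accelOffset = "numeric",
                 gyroGain = "numeric", gyroOffset = "numeric"),
  prototype(accelGain = rep(1, 3), accelOffset = rep(0, 3),
            gyroGain = rep(1, 3), gyroOffset = rep(0, 3)))

setValidity("CalibrationParams", function(object) {
  if (any(c(object@accelGain, object@gyroGain) <= 0))
    return("gains must be positive")
  if (any(!is.finite(c(object@accelGain, object@accelOffset,
                       object@gyroGain, object@gyroOffset))))
    return("calibration parameters must be finite")
  TRUE
})

#' @rdname CalibrationParams-class
#' @param accelGain,accelOffset,gyroGain,gyroOffset see slots.
#' @return A `CalibrationParams` object (identity by default).
#' @export
CalibrationParams <- function(accelGain = rep(1, 3), accelOffset = rep(0, 3),
                              gyroGain = rep(1, 3), gyroOffset = rep(0, 3))
  new("CalibrationParams", accelGain = rep_len(accelGain, 3),
      accelOffset = rep_len(accelOffset, 3),
      gyroGain = rep_len(gyroGain, 3), gyroOffset = rep_len(gyroOffset, 3))

#' Simulated human controller parameters
#'
#' A delayed proportional-derivative (PD) controller with a first-order
#' motor lag, per-step tilt jitter, and (under dual task) Poisson control
#' interruptions that freeze the commanded tilt, emulating attention being
#' captured by the concurrent cognitive task.
#'
#' @slot kp proportional gain, rad tilt per normalized displacement unit.
#' @slot kd derivative gain, rad tilt per (unit/s).
#' @slot reactionDelay sensorimotor reaction delay, s.
#' @slot motorNoiseSd SD of per-step tilt jitter, rad.
#' @slot dtInterruptionRate control interruptions per second (dual task).
#' @slot interruptionLen duration of each interruption, s.
#' @slot motorLag first-order lag time constant of tilt actuation, s.
#' @export
setClass("ControllerParams",
  representation(kp = "numeric", kd = "numeric", reactionDelay = "numeric",
                 motorNoiseSd = "numeric", dtInterruptionRate = "numeric",
                 interruptionLen = "numeric", motorLag = "numeric"),
  prototype(kp = 0.4, kd = 0.25, reactionDelay = 0.18, motorNoiseSd = 0.004,
            dtInterruptionRate = 0.25, interruptionLen = 0.8,
            motorLag = 0.15))

setValidity("ControllerParams", function(object) {
  if (object@reactionDelay < 0) return("reactionDelay must be >= 0")
  if (object@motorNoiseSd < 0) return("motorNoiseSd must be >= 0")
  if (object@dtInterruptionRate < 0)
    return("dtInterruptionRate must be >= 0")
  TRUE
})

#' @rdname ControllerParams-class
#' @param kp,kd,reactionDelay,motorNoiseSd,dtInterruptionRate,
#'   interruptionLen,motorLag see slots.
#' @return A `ControllerParams` object.
#' @export
ControllerParams <- function(kp = 0.4, kd = 0.25, reactionDelay = 0.18,
                             motorNoiseSd = 0.004, dtInterruptionRate = 0.25,
                             interruptionLen = 0.8, motorLag = 0.15)
  new("ControllerParams", kp = kp, kd = kd, reactionDelay = reactionDelay,
      motorNoiseSd = motorNoiseSd, dtInterruptionRate = dtInterruptionRate,
      interruptionLen = interruptionLen, motorLag = motorLag)

# ---- show methods --------------------------------------------------------

setMethod("show", "IMURecording", function(object) {
  n <- length(object@t)
  dur <- if (n > 1) object@t[n] - object@t[1] else 0
  cat(sprintf("IMURecording: %s task, %d samples, %.2f s\n",
              object@condition, n, dur))
})

setMethod("show", "UniformRecording", function(object) {
  cat(sprintf("UniformRecording: %s task, %d samples @ %g Hz (%.2f s)\n",
              object@condition, nrow(object@accel), object@fs,
              recordingDuration(object)))
})

setMethod("show", "Session", function(object) {
  cat(sprintf("Session %s: single=%s dual=%s\n", object@participantId,
              if (is.null(object@single)) "absent" else
                sprintf("%d samples", length(object@single@t)),
              if (is.null(object@dual)) "absent" else
                sprintf("%d samples", length(object@dual@t))))
})

setMethod("show", "BallTrajectory", function(object) {
  cat(sprintf("BallTrajectory (%s): %d samples, max r = %.3f\n",
              object@source, length(object@t),
              if (length(object@t)) max(resultantR(object)) else NA_real_))
})

setMethod("show", "TiltSeries", function(object) {
  cat(sprintf("TiltSeries: %d samples, RMS roll %.3f deg, pitch %.3f deg\n",
              length(object@t),
              sqrt(mean(object@roll^2)) * 180 / pi,
              sqrt(mean(object@pitch^2)) * 180 / pi))
})
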