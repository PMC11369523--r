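# Generics and simple accessors shared across the package.

#' Duration of a recording or trajectory in seconds
#'
#' @param x an [IMURecording-class], [UniformRecording-class] or
#'   [BallTrajectory-class].
#' @return Duration in seconds (time span of the samples).
#' @export
setGeneric("recordingDuration",
           function(x) standardGeneric("recordingDuration"))

#' @rdname recordingDuration
setMethod("recordingDuration", "IMURecording", function(x) {
  n <- length(x@t)
  if (n < 2) 0 else x@t[n] - x@t[1]
})

#' @rdname recordingDuration
setMethod("recordingDuration", "UniformRecording", function(x) {
  n <- nrow(x@accel)
  if (n < 2) 0 else (n - 1) / x@fs
})

#' @rdname recordingDuration
setMethod("recordingDuration", "BallTrajectory", function(x) {
  n <- length(x@t)
  if (n < 2) 0 else x@t[n] - x@t[1]
})

#' Sample timestamps
#' @param x an object with a time grid.
#' @return Numeric vector of timestamps in seconds.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname sampleTimes
setMethod("sampleTimes", "IMURecording", function(x) x@t)

#' @rdname sampleTimes
setMethod("sampleTimes", "UniformRecording",
          function(x) seq_len(nrow(x@accel)) / x@fs - 1 / x@fs)

#' @rdname sampleTimes
setMethod("sampleTimes", "BallTrajectory", function(x) x@t)

#' @rdname sampleTimes
setMethod("sampleTimes", "TiltSeries", function(x) x@t)

#' Accelerometer / gyroscope channel matrices
#' @param x an [IMURecording-class] or [UniformRecording-class].
#' @return n x 3 numeric matrix (m/s^2 for accel, deg/s for gyro).
#' @export
setGeneric("accelChannels", function(x) standardGeneric("accelChannels"))

#' @rdname accelChannels
setMethod("accelChannels", "IMURecording", function(x) x@accel)

#' @rdname accelChannels
setMethod("accelChannels", "UniformRecording", function(x) x@accel)

#' @rdname accelChannels
#' @export
setGeneric("gyroChannels", function(x) standardGeneric("gyroChannels"))

#' @rdname accelChannels
setMethod("gyroChannels", "IMURecording", function(x) x@gyro)

#' @rdname accelChannels
setMethod("gyroChannels", "UniformRecording", function(x) x@gyro)

#' Task condition of a recording
#' @param x an [IMURecording-class] or [UniformRecording-class].
#' @return `"single"` or `"dual"`.
#' @export
setGeneric("taskCondition", function(x) standardGeneric("taskCondition"))

#' @rdname taskCondition
setMethod("taskCondition", "IMURecording", function(x) x@condition)

#' @rdname taskCondition
setMethod("taskCondition", "UniformRecording", function(x) x@condition)

#' Resultant displacement of a ball trajectory
#'
#' @param x a [BallTrajectory-class].
#' @return Numeric vector `sqrt(x^2 + y^2)`.
#' @export
resultantR <- function(x) sqrt(x@x^2 + x@y^2)

#' Ball trajectory coordinates as a data.frame
#' @param x a [BallTrajectory-class].
#' @return data.frame with columns t, x, y, r.
#' @export
trajectoryFrame <- function(x)
  data.frame(t = x@t, x = x@x, y = x@y, r = resultantR(x))
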