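# Inertial-sensor feature suite computed from the preprocessed
# (band-passed, calibrated) recording.

.IMU_FEATURES <- c(
  "rms_accel", "rms_accel_x", "rms_accel_y", "rms_accel_z",
  "rms_gyro", "rms_gyro_x", "rms_gyro_y",
  "median_freq_accel", "sef_accel", "spec_entropy_accel",
  "median_freq_gyro", "sef_gyro", "spec_entropy_gyro",
  "sway_path_accel_x", "sway_path_accel_z",
  "sway_area_accel", "sway_jerk_accel", "ellipse95_area_accel")

.rms <- function(x) sqrt(mean(x^2))

#' All inertial-sensor features for one trial
#'
#' From the band-passed six-channel recording: RMS acceleration (vector
#' magnitude composite and per axis), RMS angular velocity (composite, x,
#' y), spectral summaries (median frequency, spectral edge frequency,
#' spectral entropy) of the acceleration and angular-velocity magnitude
#' signals, sway path lengths of the x/z acceleration axes, the
#' triangle-sum sway area rate on the (x, z) acceleration plane, a
#' dimensionless normalized sway jerk, and the area of the 95% confidence
#' ellipse of (x, z) acceleration, `pi * chi2(0.95, 2) * sqrt(det(cov))`
#' with `chi2(0.95, 2) = 5.991`.
#'
#' The normalized jerk is `sqrt(0.5 * T * integral(j_x^2 + j_z^2 dt)) / L`
#' where `j` is the time derivative of the (x, z) acceleration trace, `T`
#' the duration and `L` the trace path length, making the measure
#' dimensionless.
#'
#' @param rec a preprocessed (filtered) [UniformRecording-class].
#' @return Named list of features; spectral fields are `NA` when a channel
#'   has fewer than 256 samples or is identically zero.
#' @export
imuFeatures <- function(rec) {
  stopifnot(is(rec, "UniformRecording"))
  acc <- rec@accel; gyr <- rec@gyro
  n <- nrow(acc); fs <- rec@fs
  if (n < 2) stop("recording too short")
  T <- (n - 1) / fs
  amag <- sqrt(rowSums(acc^2))
  gmag <- sqrt(rowSums(gyr^2))
  spA <- psdSpectralFeatures(amag - mean(amag), fs)
  spG <- psdSpectralFeatures(gmag - mean(gmag), fs)
  ax <- acc[, 1] - mean(acc[, 1])
  az <- acc[, 3] - mean(acc[, 3])
  dax <- diff(ax); daz <- diff(az)
  path <- sum(sqrt(dax^2 + daz^2))
  area <- sum(abs(ax[-n] * az[-1] - ax[-1] * az[-n])) / (2 * T)
  jx <- dax * fs; jz <- daz * fs
  jerk_int <- sum(jx^2 + jz^2) / fs
  njerk <- if (path > 0) sqrt(0.5 * T * jerk_int) / path else NA_real_
  cv <- stats::cov(cbind(ax, az))
  ellipse <- pi * 5.991 * sqrt(max(det(cv), 0))
  list(
    rms_accel = .rms(amag),
    rms_accel_x = .rms(acc[, 1]), rms_accel_y = .rms(acc[, 2]),
    rms_accel_z = .rms(acc[, 3]),
    rms_gyro = .rms(gmag),
    rms_gyro_x = .rms(gyr[, 1]), rms_gyro_y = .rms(gyr[, 2]),
    median_freq_accel = spA$median_freq, sef_accel = spA$sef95,
    spec_entropy_accel = spA$spec_entropy,
    median_freq_gyro = spG$median_freq, sef_gyro = spG$sef95,
    spec_entropy_gyro = spG$spec_entropy,
    sway_path_accel_x = sum(abs(diff(acc[, 1]))),
    sway_path_accel_z = sum(abs(diff(acc[, 3]))),
    sway_area_accel = area,
    sway_jerk_accel = njerk,
    ellipse95_area_accel = ellipse)
}
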