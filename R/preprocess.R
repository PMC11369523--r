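# Signal conditioning chain: trim -> gate -> resample -> filter -> calibrate.

#' Trim artifact-prone seconds from both ends of a recording
#'
#' Removes `trim` seconds from the start and end of the trial (tablet
#' positioning artifacts) and re-zeroes timestamps to the new start.
#'
#' @param rec an [IMURecording-class].
#' @param trim seconds to exclude from each end (default 1).
#' @return Trimmed [IMURecording-class].
#' @export
trimRecording <- function(rec, trim = 1.0) {
  stopifnot(is(rec, "IMURecording"), trim >= 0)
  if (trim == 0) return(rec)
  dur <- recordingDuration(rec)
  if (dur <= 2 * trim)
    stop(sprintf("recording too short to trim: %.2f s <= 2 x %.2f s",
                 dur, trim))
  tend <- rec@t[length(rec@t)]
  keep <- rec@t >= trim & rec@t <= tend - trim
  IMURecording(rec@t[keep] - rec@t[keep][1],
               rec@accel[keep, , drop = FALSE],
               rec@gyro[keep, , drop = FALSE],
               condition = rec@condition,
               nominalDuration = rec@nominalDuration,
               deviceMeta = rec@deviceMeta)
}

#' Minimum-duration gate
#'
#' Trials shorter than `min_s` after trimming are discarded from analysis.
#' The boundary is strict: a trial of exactly `min_s` seconds is accepted.
#'
#' @param rec an [IMURecording-class] (post-trim).
#' @param min_s minimum duration in seconds (default 10).
#' @return List with elements `accepted` (logical), `duration` (s), and
#'   `reason` (character, `NA` when accepted).
#' @export
gateMinDuration <- function(rec, min_s = 10.0) {
  dur <- recordingDuration(rec)
  accepted <- dur >= min_s
  list(accepted = accepted, duration = dur,
       reason = if (accepted) NA_character_ else
         sprintf("duration %.2f s below %.2f s minimum", dur, min_s))
}

.interp_channel <- function(t, y, grid) {
  if (length(t) < 4)
    return(approx(t, y, xout = grid, rule = 2)$y)
  # shape-preserving piecewise cubic (Fritsch-Carlson)
  splinefun(t, y, method = "monoH.FC")(grid)
}

#' Resample a recording onto a uniform grid
#'
#' Tablet IMU data can be unevenly sampled, which distorts frequency-domain
#' features; each channel is interpolated (shape-preserving piecewise
#' cubic; linear for fewer than 4 samples) onto a uniform grid spanning the
#' original support. No extrapolation is performed.
#'
#' @param rec an [IMURecording-class] with strictly increasing timestamps.
#' @param fs target sampling rate in Hz (default 100).
#' @return A [UniformRecording-class] with `floor(T * fs) + 1` samples.
#' @export
resampleUniform <- function(rec, fs = 100) {
  stopifnot(is(rec, "IMURecording"), fs > 0)
  n <- length(rec@t)
  if (n < 2) stop("need at least 2 samples to resample")
  if (any(diff(rec@t) == 0)) stop("duplicate timestamps")
  t <- rec@t - rec@t[1]
  dur <- t[n]
  grid <- seq(0, by = 1 / fs, length.out = floor(dur * fs) + 1)
  acc <- vapply(1:3, function(j) .interp_channel(t, rec@accel[, j], grid),
                numeric(length(grid)))
  gyr <- vapply(1:3, function(j) .interp_channel(t, rec@gyro[, j], grid),
                numeric(length(grid)))
  colnames(acc) <- c("ax", "ay", "az"); colnames(gyr) <- c("gx", "gy", "gz")
  UniformRecording(fs = fs, accel = acc, gyro = gyr, t0Offset = rec@t[1],
                   condition = rec@condition)
}

#' Band-pass filter all six channels
#'
#' Fourth-order Butterworth IIR band-pass (default 0.1-40 Hz), applied
#' forward-backward (zero phase) so temporal features are not phase
#' shifted; the effective attenuation order doubles. DC is rejected by the
#' pass band.
#'
#' @param rec a [UniformRecording-class].
#' @param low,high band edges in Hz.
#' @param order Butterworth design order (default 4).
#' @param zero_phase apply the filter forward-backward (default TRUE).
#' @return Filtered [UniformRecording-class] of identical length.
#' @export
bandpassFilter <- function(rec, low = 0.1, high = 40, order = 4,
                           zero_phase = TRUE) {
  stopifnot(is(rec, "UniformRecording"))
  if (high >= rec@fs / 2)
    stop(sprintf("upper cutoff %g Hz >= Nyquist %g Hz", high, rec@fs / 2))
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  bf <- signal::butter(order, c(low, high) / (rec@fs / 2), type = "pass")
  apply_f <- function(x) {
    if (zero_phase) signal::filtfilt(bf, x)
    else as.numeric(signal::filter(bf, x))
  }
  acc <- apply(rec@accel, 2, apply_f)
  gyr <- apply(rec@gyro, 2, apply_f)
  UniformRecording(fs = rec@fs, accel = acc, gyro = gyr,
                   t0Offset = rec@t0Offset, condition = rec@condition)
}

#' Apply per-axis affine calibration
#'
#' Each channel becomes `gain * (channel - offset)`.
#'
#' @param rec a [UniformRecording-class].
#' @param params a [CalibrationParams-class] (identity by default).
#' @return Calibrated [UniformRecording-class].
#' @export
calibrateRecording <- function(rec, params = CalibrationParams()) {
  stopifnot(is(rec, "UniformRecording"), is(params, "CalibrationParams"))
  acc <- sweep(sweep(rec@accel, 2, params@accelOffset, "-"),
               2, params@accelGain, "*")
  gyr <- sweep(sweep(rec@gyro, 2, params@gyroOffset, "-"),
               2, params@gyroGain, "*")
  UniformRecording(fs = rec@fs, accel = acc, gyro = gyr,
                   t0Offset = rec@t0Offset, condition = rec@condition)
}

#' Estimate calibration parameters from a static epoch
#'
#' With the tablet at rest, the accelerometer magnitude should equal
#' gravity and the gyroscope should read zero. Accelerometer gains are set
#' to `g / mean(|a|)` (gravity-magnitude referencing, shared across axes);
#' gyroscope offsets are the static means.
#'
#' @param rec a static [UniformRecording-class] epoch.
#' @param g reference gravity, m/s^2.
#' @return A [CalibrationParams-class].
#' @export
estimateCalibration <- function(rec, g = 9.81) {
  stopifnot(is(rec, "UniformRecording"))
  amag <- mean(sqrt(rowSums(rec@accel^2)))
  if (amag <= 0) stop("zero accelerometer magnitude in static epoch")
  CalibrationParams(accelGain = rep(g / amag, 3),
                    gyroOffset = colMeans(rec@gyro))
}

#' Run the full conditioning chain on one trial
#'
#' trim -> minimum-duration gate -> uniform resampling -> band-pass filter
#' -> calibration. Tilt estimation needs the gravity component, which the
#' band-pass removes, so both the filtered recording and the unfiltered
#' (but resampled and calibrated) stream are returned.
#'
#' @param rec an [IMURecording-class].
#' @param trim seconds trimmed from each end.
#' @param min_s minimum post-trim duration (s).
#' @param fs target sampling rate (Hz).
#' @param band band-pass edges in Hz, `c(low, high)`.
#' @param order Butterworth design order.
#' @param zero_phase forward-backward filtering flag.
#' @param calibration a [CalibrationParams-class].
#' @return List with `accepted`, `reason`, and (when accepted) `filtered`
#'   and `unfiltered` [UniformRecording-class] objects.
#' @export
preprocessTrial <- function(rec, trim = 1.0, min_s = 10.0, fs = 100,
                            band = c(0.1, 40), order = 4, zero_phase = TRUE,
                            calibration = CalibrationParams()) {
  if (recordingDuration(rec) <= 2 * trim)
    return(list(accepted = FALSE,
                reason = sprintf("duration %.2f s too short to trim",
                                 recordingDuration(rec))))
  trimmed <- trimRecording(rec, trim)
  gate <- gateMinDuration(trimmed, min_s)
  if (!gate$accepted)
    return(list(accepted = FALSE, reason = gate$reason))
  uni <- resampleUniform(trimmed, fs)
  uni <- calibrateRecording(uni, calibration)
  filt <- bandpassFilter(uni, band[1], band[2], order, zero_phase)
  list(accepted = TRUE, reason = NA_character_,
       filtered = filt, unfiltered = uni)
}
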