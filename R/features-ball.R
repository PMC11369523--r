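# Ball-position feature suite computed from the normalized virtual-ball
# trajectory: time-in-circle scores, radial symmetry, epoch statistics,
# spectral summaries, and the standard stabilogram (center-of-pressure
# style) sway measures applied to the ball displacement.

.in_circle_threshold <- function(geom)
  geom@innerRatio * geom@outerRadius - geom@ballRadius

#' Percentage of test time spent within the inner circle
#'
#' Proportion of samples whose resultant displacement is strictly less than
#' the inner-circle radius minus the ball radius, times 100.
#'
#' @param traj a normalized [BallTrajectory-class].
#' @param geom a [TaskGeometry-class].
#' @return Percent in \[0, 100\].
#' @export
pctTimeInCircle <- function(traj, geom = TaskGeometry()) {
  n <- length(traj@t)
  if (!n) stop("empty trajectory")
  100 * sum(resultantR(traj) < .in_circle_threshold(geom)) / n
}

#' Perfect-score indicator
#'
#' TRUE when the ball lay within the inner circle for 100% of the test.
#' Note a perfect score is attainable by leaving the tablet flat on a
#' table, which motivates the perfect-score sensitivity re-run
#' ([excludePerfectScores()]).
#'
#' @inheritParams pctTimeInCircle
#' @return Logical.
#' @export
perfectScore <- function(traj, geom = TaskGeometry())
  pctTimeInCircle(traj, geom) == 100

#' Radial symmetry of the trajectory
#'
#' Sum of first-difference values of the resultant displacement from the
#' center. The default `"absolute"` mode sums `|diff(r)|` (total radial
#' movement); the `"literal"` mode sums signed differences, which
#' telescopes to `r_end - r_start`. The mode used is recorded in the
#' `"mode"` attribute of the result.
#'
#' @param traj a [BallTrajectory-class] with at least 2 samples.
#' @param mode `"absolute"` (default) or `"literal"`.
#' @return Numeric value with attribute `mode`.
#' @export
radialSymmetry <- function(traj, mode = c("absolute", "literal")) {
  mode <- match.arg(mode)
  r <- resultantR(traj)
  if (length(r) < 2) stop("need at least 2 samples")
  d <- diff(r)
  out <- if (mode == "absolute") sum(abs(d)) else sum(d)
  attr(out, "mode") <- mode
  out
}

#' Per-epoch time-in-circle statistics
#'
#' The percentage of time within the inner circle is computed for each
#' non-overlapping 5-s epoch (from t = 0); a trailing partial epoch is
#' kept when it is at least half an epoch long, dropped otherwise. Returned
#' are the mean, sample SD, and mean first difference across epochs
#' (intratest performance change); SD and first difference are `NA` with a
#' single epoch.
#'
#' @param traj a normalized [BallTrajectory-class].
#' @param geom a [TaskGeometry-class].
#' @param epoch epoch length in seconds (default 5).
#' @return List `mean`, `sd`, `first_diff` (percent), plus `epochs`, the
#'   per-epoch percentages.
#' @export
epochTimeInCircle <- function(traj, geom = TaskGeometry(), epoch = 5) {
  tt <- traj@t - traj@t[1]
  dur <- tt[length(tt)]
  if (dur < epoch / 2) stop("trajectory shorter than half an epoch")
  thr <- .in_circle_threshold(geom)
  r <- resultantR(traj)
  n_full <- floor(dur / epoch)
  rem <- dur - n_full * epoch
  n_ep <- n_full + (rem >= epoch / 2)
  if (n_ep == 0) n_ep <- 1
  pct <- vapply(seq_len(n_ep), function(k) {
    lo <- (k - 1) * epoch
    hi <- if (k == n_ep) dur + 1e-12 else k * epoch
    idx <- tt >= lo & tt < hi
    100 * sum(r[idx] < thr) / sum(idx)
  }, numeric(1))
  list(mean = mean(pct),
       sd = if (n_ep > 1) sd(pct) else NA_real_,
       first_diff = if (n_ep > 1) mean(diff(pct)) else NA_real_,
       epochs = pct)
}

#' Stabilogram sway measures of the ball displacement
#'
#' Standard center-of-pressure summary measures applied to the demeaned
#' ball displacement. For each of the resultant (`mean`), `x` and `y`
#' variants: mean sway distance (mean absolute deviation from the
#' centroid), resultant sway distance (RMS deviation), sway length (total
#' path; per axis the sum of absolute increments), sway velocity
#' (length / duration) and mean sway frequency
#' (velocity / (2 pi * mean distance), the rotational-frequency
#' convention). The sway area is the area swept per unit time by the
#' vector from the centroid (triangle-sum estimate), in units^2/s.
#'
#' @param traj a normalized [BallTrajectory-class] with >= 2 samples.
#' @return Named list of sway measures.
#' @export
swayMetricsBall <- function(traj) {
  n <- length(traj@t)
  if (n < 2) stop("need at least 2 samples")
  T <- traj@t[n] - traj@t[1]
  x <- traj@x - mean(traj@x)
  y <- traj@y - mean(traj@y)
  d <- sqrt(x^2 + y^2)
  dx <- diff(x); dy <- diff(y)
  len <- c(mean = sum(sqrt(dx^2 + dy^2)), x = sum(abs(dx)), y = sum(abs(dy)))
  mdist <- c(mean = mean(d), x = mean(abs(x)), y = mean(abs(y)))
  rdist <- c(mean = sqrt(mean(d^2)), x = sqrt(mean(x^2)), y = sqrt(mean(y^2)))
  vel <- len / T
  mfreq <- ifelse(mdist > 0, vel / (2 * pi * mdist), NA_real_)
  area <- sum(abs(x[-n] * y[-1] - x[-1] * y[-n])) / (2 * T)
  list(sway_area = area,
       mean_sway_freq = mfreq, mean_sway_dist = mdist,
       resultant_sway_dist = rdist, sway_length = len,
       sway_velocity = vel)
}

.BALL_FEATURES <- c(
  "pct_time_in_circle", "radial_symmetry",
  "epoch_pct_mean", "epoch_pct_sd", "epoch_pct_first_diff",
  "median_freq_mean", "median_freq_x", "median_freq_y",
  "sef95_mean", "sef95_x", "sef95_y",
  "sway_area",
  "mean_sway_freq_mean", "mean_sway_freq_x", "mean_sway_freq_y",
  "mean_sway_dist_mean", "mean_sway_dist_x", "mean_sway_dist_y",
  "resultant_sway_dist_mean", "resultant_sway_dist_x",
  "resultant_sway_dist_y",
  "sway_length_mean", "sway_length_x", "sway_length_y",
  "sway_velocity_mean", "sway_velocity_x", "sway_velocity_y")

#' All ball-position features for one trial
#'
#' Computes the complete ball-displacement feature suite: percentage of
#' time in the inner circle, radial symmetry, 5-s epoch statistics,
#' median frequency and SEF95 of the displacement (resultant, x, y), and
#' the stabilogram sway measures. `radial_frequency` is an alias of
#' `mean_sway_freq_mean` (mean rotational sway frequency of the
#' resultant).
#'
#' @param traj a normalized [BallTrajectory-class].
#' @param geom a [TaskGeometry-class].
#' @param fs sampling rate of the trajectory grid in Hz.
#' @return Named list: numeric features plus logical `perfect_score`.
#' @export
ballFeatures <- function(traj, geom = TaskGeometry(), fs = 100) {
  ep <- epochTimeInCircle(traj, geom)
  sw <- swayMetricsBall(traj)
  x <- traj@x - mean(traj@x)
  y <- traj@y - mean(traj@y)
  r <- sqrt(x^2 + y^2)
  spR <- psdSpectralFeatures(r, fs)
  spX <- psdSpectralFeatures(x, fs)
  spY <- psdSpectralFeatures(y, fs)
  out <- list(
    pct_time_in_circle = pctTimeInCircle(traj, geom),
    radial_symmetry = as.numeric(radialSymmetry(traj)),
    epoch_pct_mean = ep$mean, epoch_pct_sd = ep$sd,
    epoch_pct_first_diff = ep$first_diff,
    median_freq_mean = spR$median_freq, median_freq_x = spX$median_freq,
    median_freq_y = spY$median_freq,
    sef95_mean = spR$sef95, sef95_x = spX$sef95, sef95_y = spY$sef95,
    sway_area = sw$sway_area,
    mean_sway_freq_mean = sw$mean_sway_freq[["mean"]],
    mean_sway_freq_x = sw$mean_sway_freq[["x"]],
    mean_sway_freq_y = sw$mean_sway_freq[["y"]],
    mean_sway_dist_mean = sw$mean_sway_dist[["mean"]],
    mean_sway_dist_x = sw$mean_sway_dist[["x"]],
    mean_sway_dist_y = sw$mean_sway_dist[["y"]],
    resultant_sway_dist_mean = sw$resultant_sway_dist[["mean"]],
    resultant_sway_dist_x = sw$resultant_sway_dist[["x"]],
    resultant_sway_dist_y = sw$resultant_sway_dist[["y"]],
    sway_length_mean = sw$sway_length[["mean"]],
    sway_length_x = sw$sway_length[["x"]],
    sway_length_y = sw$sway_length[["y"]],
    sway_velocity_mean = sw$sway_velocity[["mean"]],
    sway_velocity_x = sw$sway_velocity[["x"]],
    sway_velocity_y = sw$sway_velocity[["y"]])
  out$perfect_score <- out$pct_time_in_circle == 100
  out
}
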