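# Session file I/O. The on-disk dialect is a self-contained JSON schema:
#   { "participant_id": str,
#     "trials": [ { "condition": "single"|"dual",
#                   "samples": [ {"t","ax","ay","az","gx","gy","gz"}, ... ],
#                   "ball":    [ {"t","x","y"}, ... ]   (optional) } ] }
# Units on disk: accelerometer m/s^2, gyroscope deg/s, time = float seconds
# from trial start. A permissive variant with per-channel arrays
# ("t":[...], "ax":[...], ...) is also accepted.

.SAMPLE_KEYS <- c("t", "ax", "ay", "az", "gx", "gy", "gz")

.parse_trial <- function(tr, path, convert_units = FALSE) {
  if (is.null(tr$condition) ||
      !tr$condition %in% c("single", "dual"))
    stop(sprintf("%s: trial key 'condition' missing or invalid", path))
  if (is.null(tr$samples))
    stop(sprintf("%s: trial key 'samples' missing", path))
  s <- tr$samples
  if (is.data.frame(s) && nrow(s) == 1 &&
      any(vapply(s, is.list, logical(1))))
    s <- lapply(s, function(col) unlist(col[[1]]))  # per-channel arrays,
                                                    # simplified to 1 row
  if (is.data.frame(s)) {               # array-of-objects, simplified
    df <- s
  } else if (is.list(s) && !is.null(names(s))) {  # per-channel arrays
    df <- as.data.frame(s[.SAMPLE_KEYS])
  } else stop(sprintf("%s: trial key 'samples' has unknown layout", path))
  miss <- setdiff(.SAMPLE_KEYS, names(df))
  if (length(miss))
    stop(sprintf("%s: sample key '%s' missing", path, miss[1]))
  df <- df[.SAMPLE_KEYS]
  if (any(!vapply(df, is.numeric, logical(1))))
    stop(sprintf("%s: non-numeric value under key 'samples'", path))
  if (any(diff(df$t) <= 0))
    stop(sprintf("%s: non-monotone timestamps in %s trial", path,
                 tr$condition))
  acc <- as.matrix(df[c("ax", "ay", "az")])
  gyr <- as.matrix(df[c("gx", "gy", "gz")])
  if (convert_units) {                  # from g and rad/s to m/s^2, deg/s
    acc <- acc * 9.80665
    gyr <- gyr * 180 / pi
  }
  meta <- tr$device_meta
  if (is.null(meta)) meta <- list()
  ball <- NULL
  if (!is.null(tr$ball)) {
    ball <- as.data.frame(tr$ball)
    if (!all(c("t", "x", "y") %in% names(ball)))
      stop(sprintf("%s: trial key 'ball' must contain t, x, y", path))
    ball <- ball[c("t", "x", "y")]
  }
  list(rec = IMURecording(df$t, acc, gyr, condition = tr$condition,
                          deviceMeta = as.list(meta)),
       ball = ball)
}

#' Read a trial session from JSON
#'
#' Parses a session file holding up to two ball-balancing trials (single and
#' dual task) with their IMU sample streams and, when the app logged them,
#' the on-screen ball positions. Timestamps are validated to be strictly
#' increasing; ordering violations are errors, never silent sorts.
#'
#' @param path path to a session JSON file.
#' @param convert_units if TRUE, accelerometer values on disk are taken to
#'   be in g and gyroscope values in rad/s and are converted to the
#'   reference units (m/s^2, deg/s).
#' @return A [Session-class] object.
#' @export
readSession <- function(path, convert_units = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such session file: %s", path))
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                 error = function(e)
                   stop(sprintf("%s: malformed JSON (%s)", path,
                                conditionMessage(e))))
  if (is.null(js$participant_id))
    stop(sprintf("%s: key 'participant_id' missing", path))
  trials <- js$trials
  if (is.null(trials) || (is.data.frame(trials) && !nrow(trials)) ||
      (!is.data.frame(trials) && !length(trials)))
    stop(sprintf("%s: key 'trials' missing or empty", path))
  # fromJSON may simplify trials into a data.frame of list-columns
  if (is.data.frame(trials))
    trials <- lapply(seq_len(nrow(trials)), function(i) {
      tr <- lapply(trials, function(col) {
        if (is.data.frame(col)) col[i, , drop = FALSE] else col[[i]]
      })
      tr[!vapply(tr, function(v) is.null(v) ||
                   (length(v) == 1 && !is.list(v) && is.na(v)), logical(1))]
    })
  parsed <- lapply(trials, .parse_trial, path = path,
                   convert_units = convert_units)
  conds <- vapply(parsed, function(p) p$rec@condition, character(1))
  if (anyDuplicated(conds))
    stop(sprintf("%s: duplicate trial condition '%s'", path,
                 conds[duplicated(conds)][1]))
  pick <- function(cond) {
    i <- match(cond, conds)
    if (is.na(i)) list(rec = NULL, ball = NULL) else parsed[[i]]
  }
  s <- pick("single"); d <- pick("dual")
  Session(js$participant_id, single = s$rec, dual = d$rec,
          singleBall = s$ball, dualBall = d$ball)
}

.trial_json <- function(rec, ball) {
  out <- list(
    condition = jsonlite::unbox(rec@condition),
    samples = data.frame(t = rec@t,
                         ax = rec@accel[, 1], ay = rec@accel[, 2],
                         az = rec@accel[, 3],
                         gx = rec@gyro[, 1], gy = rec@gyro[, 2],
                         gz = rec@gyro[, 3]))
  if (!is.null(ball)) out$ball <- ball[c("t", "x", "y")]
  if (length(rec@deviceMeta))
    out$device_meta <- lapply(rec@deviceMeta,
                              function(v) jsonlite::unbox(as.character(v)))
  out
}

#' Write a session to canonical JSON
#'
#' Serializes in a fixed key order at full double precision, so that
#' `writeSession(readSession(f))` is byte-identical to a canonically
#' written `f`.
#'
#' @param session a [Session-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path) {
  trials <- list()
  if (!is.null(session@single))
    trials <- c(trials, list(.trial_json(session@single, session@singleBall)))
  if (!is.null(session@dual))
    trials <- c(trials, list(.trial_json(session@dual, session@dualBall)))
  obj <- list(participant_id = jsonlite::unbox(session@participantId),
              trials = trials)
  json <- jsonlite::toJSON(obj, digits = NA, dataframe = "rows",
                           auto_unbox = FALSE, pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

.COHORT_LEVELS <- c("healthy", "MCI", "ADRD", "missing")
.META_COLS <- c("participant_id", "age", "sex", "cohort", "mmse_total",
                "ravlt_total", "ravlt_long_delay", "faq_total")

#' Read the participant metadata table
#'
#' CSV with header `participant_id,age,sex,cohort,mmse_total,ravlt_total,
#' ravlt_long_delay,faq_total`. Cohort is one of healthy/MCI/ADRD; an empty
#' cell yields cohort `"missing"` (participants without a valid cohort
#' status label are retained).
#'
#' @param path path to the metadata CSV.
#' @param strict_range if TRUE, out-of-protocol ages (outside 60-85) are
#'   collected as warnings in the `"range_warnings"` attribute; records are
#'   always kept.
#' @return data.frame, one row per participant; cohort and sex as factors.
#' @export
readMetadata <- function(path, strict_range = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.META_COLS, names(df))
  if (length(miss))
    stop(sprintf("%s: metadata column '%s' missing", path, miss[1]))
  df <- df[.META_COLS]
  df$cohort[is.na(df$cohort) | df$cohort == ""] <- "missing"
  bad <- setdiff(unique(df$cohort), .COHORT_LEVELS)
  if (length(bad))
    stop(sprintf("unknown cohort token '%s'; allowed: %s", bad[1],
                 paste(.COHORT_LEVELS, collapse = ", ")))
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (any(!is.na(df$mmse_total) & (df$mmse_total < 0 | df$mmse_total > 30)))
    stop("mmse_total must lie in 0-30")
  df$cohort <- factor(df$cohort, levels = .COHORT_LEVELS)
  df$sex <- factor(df$sex, levels = c("male", "female"))
  warns <- character(0)
  if (strict_range) {
    out <- which(df$age < 60 | df$age > 85)
    if (length(out))
      warns <- sprintf("participant %s: age %g outside study range 60-85",
                       df$participant_id[out], df$age[out])
  }
  attr(df, "range_warnings") <- warns
  df
}

#' Write a participant metadata table
#' @param metadata data.frame as returned by [readMetadata()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMetadata <- function(metadata, path) {
  write.csv(metadata[.META_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
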