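# Per-participant assembly of single-task, dual-task and dual-task-cost
# feature rows into a BallFeatureTable (SummarizedExperiment subclass:
# assays st/dt/dtc, rows = features, columns = participants, colData =
# participant metadata).

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Feature table for a cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] with assays `st`, `dt`
#' and `dtc` (features x participants) and participant metadata (age, sex,
#' cohort, MMSE, RAVLT, FAQ, perfect-score flags) as `colData`. Build with
#' [buildFeatureTable()]; flatten with [featureFrame()].
#'
#' @export
setClass("BallFeatureTable", contains = "SummarizedExperiment")

setValidity("BallFeatureTable", function(object) {
  if (!all(c("st", "dt", "dtc") %in% names(assays(object))))
    return("assays st, dt and dtc are required")
  TRUE
})

#' Dual-task cost of a feature
#'
#' Percentage performance change from single task (ST) to dual task (DT):
#' `-100 * (dt - st) / st`. For a "higher is better" metric a performance
#' drop under dual task therefore gives a positive cost. A zero ST value
#' yields a missing cost (never +/-Inf).
#'
#' @param st,dt feature values under single- and dual-task conditions
#'   (vectorized).
#' @return Numeric cost in percent; `NA` where `st` is 0 or either value
#'   is missing.
#' @export
dualTaskCost <- function(st, dt) {
  out <- -100 * (dt - st) / st
  out[!is.na(st) & st == 0] <- NA_real_
  out
}

.all_features <- function() c(.BALL_FEATURES, .IMU_FEATURES)

.trial_features <- function(rec, geom, phys, config, ball_recorded = NULL) {
  pp <- preprocessTrial(rec, trim = config$trim_s, min_s = config$min_s,
                        fs = config$fs, band = config$band,
                        order = config$order,
                        zero_phase = config$zero_phase)
  if (!pp$accepted)
    return(list(accepted = FALSE, reason = pp$reason, values = NULL,
                perfect = NA))
  if (identical(config$ball_source, "recorded") && !is.null(ball_recorded)) {
    traj <- BallTrajectory(ball_recorded$t, ball_recorded$x,
                           ball_recorded$y, source = "recorded")
  } else {
    # ball trajectory covers the whole test: derived from the untrimmed
    # stream so the known initial state (ball at center, at rest, at the
    # start of the trial) applies; trimming stays in the IMU-feature path
    uni_full <- resampleUniform(rec, config$fs)
    traj <- deriveBallTrajectory(uni_full, geom, phys)
  }
  bf <- ballFeatures(traj, geom, fs = config$fs)
  im <- imuFeatures(pp$filtered)
  perfect <- bf$perfect_score
  bf$perfect_score <- NULL
  vals <- unlist(c(bf, im))[.all_features()]
  list(accepted = TRUE, reason = NA_character_, values = vals,
       perfect = perfect)
}

.default_table_config <- function()
  list(trim_s = 1, min_s = 10, fs = 100, band = c(0.1, 40), order = 4,
       zero_phase = TRUE, ball_source = "derived")

#' Build the cohort feature table
#'
#' Runs every session through the conditioning chain, derives the ball
#' trajectory, extracts the ball-position and inertial-sensor feature
#' suites for each condition, and computes the dual-task cost per feature.
#' Trials rejected by the duration gate produce missing condition columns;
#' a run manifest (counts accepted/rejected, perfect-score counts,
#' rejection reasons) is stored in `metadata(x)$manifest`.
#'
#' @param sessions list of [Session-class] objects.
#' @param metadata participant metadata data.frame ([readMetadata()]).
#' @param geom a [TaskGeometry-class].
#' @param phys a [PhysicsParams-class].
#' @param config list of preprocessing options; see defaults in the source
#'   (`trim_s`, `min_s`, `fs`, `band`, `order`, `zero_phase`,
#'   `ball_source`).
#' @return A [BallFeatureTable-class].
#' @export
buildFeatureTable <- function(sessions, metadata, geom = TaskGeometry(),
                              phys = PhysicsParams(), config = list()) {
  config <- modifyList(.default_table_config(), config)
  ids <- vapply(sessions, function(s) s@participantId, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate participant_id '%s'", ids[duplicated(ids)][1]))
  nf <- length(.all_features())
  st <- dt <- matrix(NA_real_, nf, length(ids),
                     dimnames = list(.all_features(), ids))
  perfect_st <- perfect_dt <- rep(NA, length(ids))
  rejections <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    for (cond in c("single", "dual")) {
      rec <- slot(s, cond)
      if (is.null(rec)) next
      ball <- if (cond == "single") s@singleBall else s@dualBall
      res <- .trial_features(rec, geom, phys, config, ball)
      if (!res$accepted) {
        rejections[[length(rejections) + 1L]] <-
          list(participant_id = ids[i], condition = cond,
               reason = res$reason)
        next
      }
      if (cond == "single") {
        st[, i] <- res$values; perfect_st[i] <- res$perfect
      } else {
        dt[, i] <- res$values; perfect_dt[i] <- res$perfect
      }
    }
  }
  dtc <- dualTaskCost(st, dt)
  m <- metadata[match(ids, metadata$participant_id), , drop = FALSE]
  cd <- DataFrame(m, perfect_score_st = perfect_st,
                  perfect_score_dt = perfect_dt, row.names = ids)
  se <- SummarizedExperiment(assays = list(st = st, dt = dt, dtc = dtc),
                             colData = cd)
  ft <- new("BallFeatureTable", se)
  metadata(ft)$manifest <- list(
    n_sessions = length(ids),
    n_trials_in = sum(vapply(sessions, function(s)
      (!is.null(s@single)) + (!is.null(s@dual)), numeric(1))),
    n_trials_rejected = length(rejections),
    n_perfect_st = sum(perfect_st, na.rm = TRUE),
    n_perfect_dt = sum(perfect_dt, na.rm = TRUE),
    rejections = rejections,
    config = config)
  metadata(ft)$radial_symmetry_mode <- "absolute"
  ft
}

#' Flatten a feature table to one row per participant
#'
#' Columns are the features suffixed `_st`, `_dt`, `_dtc`, followed by the
#' participant metadata, matching the serialized CSV layout.
#'
#' @param ft a [BallFeatureTable-class].
#' @return data.frame keyed by `participant_id`.
#' @export
featureFrame <- function(ft) {
  stopifnot(is(ft, "BallFeatureTable"))
  blocks <- lapply(c("st", "dt", "dtc"), function(a) {
    m <- t(assay(ft, a))
    colnames(m) <- paste0(colnames(m), "_", a)
    m
  })
  cd <- as.data.frame(colData(ft))
  cbind(data.frame(participant_id = colnames(ft),
                   stringsAsFactors = FALSE),
        do.call(cbind, blocks), cd[setdiff(names(cd), "participant_id")],
        row.names = NULL)
}

#' Rebuild a feature table from its flattened CSV layout
#'
#' Inverse of [writeFeatureTable()] / [featureFrame()].
#'
#' @param x path to a features CSV, or the flat data.frame itself.
#' @return A [BallFeatureTable-class].
#' @export
readFeatureTable <- function(x) {
  df <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
  ids <- df$participant_id
  asy <- lapply(c(st = "st", dt = "dt", dtc = "dtc"), function(a) {
    cols <- paste0(.all_features(), "_", a)
    m <- t(as.matrix(df[cols]))
    dimnames(m) <- list(.all_features(), ids)
    m
  })
  meta_cols <- setdiff(names(df), unlist(lapply(c("st", "dt", "dtc"),
    function(a) paste0(.all_features(), "_", a))))
  cd <- df[meta_cols]
  cd$sex <- factor(cd$sex, levels = c("male", "female"))
  cd$cohort <- factor(cd$cohort, levels = .COHORT_LEVELS)
  se <- SummarizedExperiment(assays = asy,
                             colData = DataFrame(cd, row.names = ids))
  new("BallFeatureTable", se)
}

#' Write the flattened feature table to CSV
#' @param ft a [BallFeatureTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(ft, path) {
  write.csv(featureFrame(ft), path, row.names = FALSE)
  invisible(path)
}

#' Perfect-score sensitivity subset
#'
#' Returns the table restricted to participants without a perfect score in
#' the given conditions, supporting the sensitivity re-run that checks
#' whether perfect-score tests (attainable by resting the tablet flat)
#' affect the findings. The main table is left untouched.
#'
#' @param ft a [BallFeatureTable-class].
#' @param conditions conditions whose perfect scores trigger exclusion
#'   (default `"st"`; any of `"st"`, `"dt"`).
#' @return A subset [BallFeatureTable-class].
#' @export
excludePerfectScores <- function(ft, conditions = "st") {
  stopifnot(is(ft, "BallFeatureTable"))
  drop <- rep(FALSE, ncol(ft))
  if ("st" %in% conditions)
    drop <- drop | (!is.na(ft$perfect_score_st) & ft$perfect_score_st)
  if ("dt" %in% conditions)
    drop <- drop | (!is.na(ft$perfect_score_dt) & ft$perfect_score_dt)
  ft[, !drop]
}
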