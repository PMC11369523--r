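# End-to-end orchestration: simulate -> extract features -> stats ->
# classify, driven by a YAML (or list) config with a single seed.

#' Default pipeline configuration
#'
#' Nested config understood by [runPipeline()]; serializable as YAML.
#' Sections: `seed`; `simulate` (cohort counts, calibrate flag);
#' `preprocess` (`fs`, `trim_s`, `min_duration_s`, `band`, `order`,
#' `zero_phase`); `ball` (`source`); `geometry` (`inner_ratio`,
#' `ball_radius`); `physics` (`g`, `rolling_factor`, `damping`,
#' `screen_scale`, `boundary`); `stats` (`features`); `classify`
#' (`schemes`, `scopes`, `folds`, `features`, `max_candidates`); `out`
#' (output directory).
#'
#' @return Nested list of defaults.
#' @export
defaultConfig <- function() {
  list(seed = 1,
       simulate = list(enabled = TRUE, calibrate = FALSE,
                       n_per_cohort = c(healthy = 132, MCI = 116,
                                        ADRD = 126),
                       n_missing_label = 1),
       input = list(sessions_dir = NULL, metadata = NULL),
       preprocess = list(fs = 100, trim_s = 1, min_duration_s = 10,
                         band = c(0.1, 40), order = 4, zero_phase = TRUE),
       ball = list(source = "derived"),
       geometry = list(inner_ratio = 0.5, ball_radius = 0.05),
       physics = list(g = 9.81, rolling_factor = 1, damping = 0.05,
                      screen_scale = 0.585, boundary = "clamp"),
       stats = list(enabled = TRUE,
                    features = c("pct_time_in_circle", "rms_accel",
                                 "median_freq_accel", "sway_velocity_mean",
                                 "mean_sway_freq_mean")),
       classify = list(enabled = TRUE, schemes = "cohort2", scopes = "dt",
                       folds = 10, features = NULL, max_candidates = 40),
       out = "dtball-run")
}

.cfg_geom <- function(config)
  TaskGeometry(innerRatio = config$geometry$inner_ratio,
               ballRadius = config$geometry$ball_radius)

.cfg_phys <- function(config)
  PhysicsParams(g = config$physics$g,
                rollingFactor = config$physics$rolling_factor,
                damping = config$physics$damping,
                screenScale = config$physics$screen_scale,
                boundary = config$physics$boundary)

.log_stage <- function(quiet, stage, ...) {
  if (!quiet)
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess + feature extraction ->
#' statistics -> classification, writing the feature table CSV, the tidy
#' stats report, classifier report JSONs and a run manifest into the
#' output directory. All randomness flows from the single `seed` entry.
#'
#' @param config a config list ([defaultConfig()]), or the path of a YAML
#'   file holding one; partial configs are completed with the defaults.
#' @param quiet suppress progress messages.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` as well.
#' @export
runPipeline <- function(config = defaultConfig(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(defaultConfig(), config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  geom <- .cfg_geom(config); phys <- .cfg_phys(config)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, expr) {
    s <- Sys.time()
    out <- expr
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }

  if (isTRUE(config$simulate$enabled)) {
    npc <- unlist(config$simulate$n_per_cohort)
    if (is.null(names(npc)))        # YAML may drop vector names
      names(npc) <- c("healthy", "MCI", "ADRD")
    cc <- defaultCohortConfig(
      n_per_cohort = npc,
      n_missing_label = config$simulate$n_missing_label,
      seed = config$seed)
    cc$geom <- geom; cc$phys <- phys
    if (isTRUE(config$simulate$calibrate))
      cc <- tick("calibrate", calibrateCohort(cc, seed = config$seed))
    .log_stage(quiet, "simulate", "generating %d participants",
               sum(unlist(config$simulate$n_per_cohort)) +
                 config$simulate$n_missing_label)
    cohort <- tick("simulate", simulateCohort(cc))
    sessions <- cohort$sessions
    metadata <- cohort$metadata
  } else {
    files <- list.files(config$input$sessions_dir, pattern = "\\.json$",
                        full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    .log_stage(quiet, "load", "reading %d session files", length(files))
    sessions <- tick("load", lapply(files, readSession))
    metadata <- readMetadata(config$input$metadata)
  }

  .log_stage(quiet, "extract", "building feature table")
  ft <- tick("extract", buildFeatureTable(
    sessions, metadata, geom, phys,
    config = list(trim_s = config$preprocess$trim_s,
                  min_s = config$preprocess$min_duration_s,
                  fs = config$preprocess$fs,
                  band = config$preprocess$band,
                  order = config$preprocess$order,
                  zero_phase = config$preprocess$zero_phase,
                  ball_source = config$ball$source)))
  ft_path <- file.path(config$out, "features.csv")
  writeFeatureTable(ft, ft_path)
  man_ft <- metadata(ft)$manifest
  outputs <- ft_path

  stats_path <- NULL
  if (isTRUE(config$stats$enabled)) {
    n_ok <- sum(colSums(!is.na(assay(ft, "st"))) > 0 |
                colSums(!is.na(assay(ft, "dt"))) > 0)
    if (n_ok == 0) stop("stats stage: no analyzable trials after gating")
    .log_stage(quiet, "stats", "tidy report over %d features",
               length(config$stats$features))
    rep_df <- tick("stats", statsReport(ft,
                                        features = config$stats$features))
    stats_path <- file.path(config$out, "stats.csv")
    write.csv(rep_df, stats_path, row.names = FALSE)
    outputs <- c(outputs, stats_path)
  }

  reports <- list()
  if (isTRUE(config$classify$enabled)) {
    for (scheme in config$classify$schemes)
      for (scope in config$classify$scopes) {
        .log_stage(quiet, "classify", "scheme=%s scope=%s", scheme, scope)
        rp <- tick(paste0("classify_", scheme, "_", scope),
                   stratifiedRun(ft, scheme = scheme, scope = scope,
                                 folds = config$classify$folds,
                                 seed = config$seed,
                                 features = config$classify$features,
                                 max_candidates =
                                   config$classify$max_candidates))
        p <- file.path(config$out,
                       sprintf("classifier_%s_%s.json", scheme, scope))
        writeClassifierReport(rp, p)
        reports[[paste(scheme, scope, sep = "_")]] <- rp
        outputs <- c(outputs, p)
      }
  }

  manifest <- list(
    seed = config$seed,
    config_hash = .config_hash(config),
    counts = list(sessions_in = length(sessions),
                  trials_in = man_ft$n_trials_in,
                  trials_rejected = man_ft$n_trials_rejected,
                  trials_analyzed = man_ft$n_trials_in -
                    man_ft$n_trials_rejected,
                  perfect_score_st = man_ft$n_perfect_st,
                  perfect_score_dt = man_ft$n_perfect_dt),
    rejections = man_ft$rejections,
    timings_s = timings,
    outputs = outputs,
    total_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(manifest, list(feature_table = ft, reports = reports)))
}

.config_hash <- function(config) {
  # stable content hash without external digest dependencies
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA, force = TRUE)
  raw <- utils::head(charToRaw(as.character(s)), 100000L)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% 0xFFFFFFF)
}
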