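# End-to-end pipeline: simulate -> trim -> fuse -> featurize -> benchmark,
# with a run directory of tables, ROC point sets, per-trial joint angles and
# a machine-readable manifest. A thin command-line wrapper over these
# functions ships in inst/cli/imuwrist.R.

#' Pipeline configuration
#'
#' Bundles the stage configurations. Any component can be overridden; the
#' defaults reproduce the package's reference synthetic study.
#'
#' @param cohort a [cohort_spec()].
#' @param trim_seconds startup trim, seconds.
#' @param fusion a [fusion_config()].
#' @param drift a [drift_config()].
#' @param feature_mode harmonic selection mode, see [extract_harmonics()].
#' @param cv a [cv_config()].
#' @param classifiers character vector of classifier names.
#' @param out_dir output run directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            trim_seconds = 1,
                            fusion = fusion_config(),
                            drift = drift_config(),
                            feature_mode = "dominant",
                            cv = cv_config(),
                            classifiers = classifier_names(),
                            out_dir = tempfile("imuwrist_run_")) {
  structure(list(cohort = cohort, trim_seconds = trim_seconds,
                 fusion = fusion, drift = drift,
                 feature_mode = feature_mode, cv = cv,
                 classifiers = classifiers, out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Recognised top-level blocks: `cohort`, `fusion`, `drift`, `cv`,
#' `trim_seconds`, `feature_mode`, `classifiers`, `out_dir`; unknown keys are
#' rejected so typos fail loudly. Missing blocks take package defaults.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("cohort", "fusion", "drift", "cv", "trim_seconds", "feature_mode",
             "classifiers", "out_dir", "noise")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  noise <- if (!is.null(raw$noise)) do.call(sensor_noise_model, raw$noise)
           else sensor_noise_model()
  cohort_args <- raw$cohort %||% list()
  cohort_args$noise <- noise
  args <- list(
    cohort = do.call(cohort_spec, cohort_args),
    fusion = do.call(fusion_config, raw$fusion %||% list()),
    drift = do.call(drift_config, raw$drift %||% list()),
    cv = do.call(cv_config, raw$cv %||% list())
  )
  if (!is.null(raw$trim_seconds)) args$trim_seconds <- raw$trim_seconds
  if (!is.null(raw$feature_mode)) args$feature_mode <- raw$feature_mode
  if (!is.null(raw$classifiers)) args$classifiers <- unlist(raw$classifiers)
  if (!is.null(raw$out_dir)) args$out_dir <- raw$out_dir
  do.call(pipeline_config, args)
}

#' Range-of-motion report for a set of trials
#'
#' Runs the fusion pipeline on each trial and tabulates the detected maximum
#' joint angle and range of motion.
#'
#' @param trials list of `raw_trial` objects.
#' @param config a [pipeline_config()] (fusion/drift/trim settings are used).
#' @return Data frame with columns `trial`, `label`, `max_angle`, `range`
#'   (degrees).
#' @export
rom_report <- function(trials, config = pipeline_config()) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    if (config$trim_seconds > 0) tr <- trim_startup(tr, config$trim_seconds)
    ja <- trial_joint_angle(tr, config$fusion, config$drift)
    data.frame(trial = tr$meta$trial_id %||% sprintf("trial_%03d", i),
               label = if (is.null(tr$label)) NA_integer_ else tr$label,
               max_angle = ja$max_angle, range = ja$range,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' simulate -> trim -> fuse (per-trial joint angles + ROM table) ->
#' featurize (270-feature matrix) -> benchmark (CV accuracy/AUC/ROC), writing
#' all artifacts and a run manifest into `config$out_dir`. Identical config
#' and seeds reproduce identical outputs. Stage failures abort with a
#' stage-tagged error.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return The output directory path, invisibly; artifacts: `benchmark.csv`,
#'   `roc_*.csv`, `rom.csv`, `features.csv`, `features.arff`,
#'   `angles/trial_*.csv`, `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("simulate: %d CP-like + %d typical trials",
      config$cohort$n_cp, config$cohort$n_typical)
  trials <- stage("simulate", generate_cohort(config$cohort))

  trimmed <- stage("trim", lapply(trials, trim_startup, config$trim_seconds))

  say("fuse: joint angles for %d trials", length(trimmed))
  rom <- stage("fuse", rom_report(trimmed,
                                  pipeline_config(cohort = config$cohort,
                                                  trim_seconds = 0,
                                                  fusion = config$fusion,
                                                  drift = config$drift)))
  utils::write.csv(rom, file.path(out, "rom.csv"), row.names = FALSE)
  ang_dir <- file.path(out, "angles")
  dir.create(ang_dir, showWarnings = FALSE)
  stage("fuse", for (i in seq_along(trimmed)) {
    ja <- trial_joint_angle(trimmed[[i]], config$fusion, config$drift)
    utils::write.csv(data.frame(time_s = ja$t, angle_deg = ja$angle),
                     file.path(ang_dir, sprintf("%s.csv", rom$trial[i])),
                     row.names = FALSE)
  })

  say("featurize: 270-dimensional vectors")
  data <- stage("featurize", build_dataset(trimmed, mode = config$feature_mode))
  write_dataset_csv(data, file.path(out, "features.csv"))
  write_dataset_arff(data, file.path(out, "features.arff"))

  say("bench: %d classifiers, %d-fold CV", length(config$classifiers), config$cv$k)
  table <- stage("bench", run_cv(data, config$classifiers, config$cv))
  write_benchmark_csv(table, out)

  manifest <- list(
    package = "imuwrist",
    version = as.character(utils::packageVersion("imuwrist")),
    r_version = R.version.string,
    seed = config$cohort$seed,
    cv_seed = config$cv$seed,
    n_trials = length(trials),
    trim_seconds = config$trim_seconds,
    feature_mode = config$feature_mode,
    classifiers = config$classifiers,
    cohort = config$cohort[c("n_cp", "n_typical", "cp_peak_angle",
                             "typical_peak_angle", "cp_speed", "typical_speed",
                             "tremor_amplitude", "tremor_frequency",
                             "duration", "fs")],
    fusion = unclass(config$fusion)[c("h", "l")],
    drift = unclass(config$drift)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: %s", out)
  invisible(out)
}
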