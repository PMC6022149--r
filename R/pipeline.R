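log_msg <- function(...) message(sprintf("[harfall] %s", sprintf(...)))

write_json_artifact <- function(x, path, config) {
  x$config <- unclass(config)
  x$config_hash <- config_hash(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

check_artifact_hash <- function(doc, config, what) {
  if (!is.null(doc$config_hash) &&
      !identical(doc$config_hash, config_hash(config)))
    stop(what, " was produced under a different configuration (hash ",
         doc$config_hash, " vs ", config_hash(config),
         "); refusing to mix artifacts")
}

#' Run one pipeline command
#'
#' Programmatic equivalent of the command-line interface. Commands:
#' \describe{
#'   \item{simulate}{generate a synthetic cohort; writes one labelled
#'     stream CSV per subject plus a cohort manifest JSON into
#'     `paths$outdir`.}
#'   \item{features}{read a stream CSV (`paths$input`), extract window
#'     features, write them as CSV (`paths$out`).}
#'   \item{annotate}{seeded K-Means annotation of `paths$input` feature
#'     CSV using `paths$seed` labeled feature CSV; writes labeled CSV to
#'     `paths$out`.}
#'   \item{filter}{LLOF-filter a labeled feature CSV (`paths$input`);
#'     kept rows go to `paths$out`, removed rows with scores to
#'     `paths$removed` (default alongside).}
#'   \item{train}{full personalized training: `paths$input` raw stream
#'     CSV + `paths$seed` labeled feature CSV -> classifier JSON at
#'     `paths$out`.}
#'   \item{classify}{apply `paths$model` to `paths$input` stream CSV;
#'     per-window predictions CSV at `paths$out`.}
#'   \item{evaluate}{leave-one-out comparison on a simulated cohort
#'     directory (`paths$cohort`, as written by `simulate`); CSV + JSON
#'     summary at `paths$out` / `paths$out_json`.}
#' }
#' All randomness is governed by `config$seed`; a given config and seed
#' reproduce artifacts byte-identically. Every JSON artifact embeds the
#' effective config and its hash, and `evaluate`/`classify` refuse
#' artifacts whose hash disagrees with the current config.
#'
#' @param command one of `simulate`, `features`, `annotate`, `filter`,
#'   `train`, `classify`, `evaluate`.
#' @param config a [har_config()].
#' @param paths named list of input/output paths (see command list).
#' @return command-specific result, invisibly.
#' @export
run_pipeline <- function(command, config = har_config(), paths = list()) {
  t0 <- proc.time()[["elapsed"]]
  result <- switch(
    command,
    simulate = pipeline_simulate(config, paths),
    features = pipeline_features(config, paths),
    annotate = pipeline_annotate(config, paths),
    filter = pipeline_filter(config, paths),
    train = pipeline_train(config, paths),
    classify = pipeline_classify(config, paths),
    evaluate = pipeline_evaluate(config, paths),
    stop("unknown command: ", command)
  )
  log_msg("%s finished in %.1f s", command, proc.time()[["elapsed"]] - t0)
  invisible(result)
}

need_path <- function(paths, key, command) {
  if (is.null(paths[[key]]))
    stop("command '", command, "' needs paths$", key)
  paths[[key]]
}

pipeline_simulate <- function(config, paths) {
  outdir <- need_path(paths, "outdir", "simulate")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n_subjects <- paths$n_subjects %||% 10
  shift <- paths$subject_shift %||% 0.3
  cohort <- make_cohort(n_subjects = n_subjects,
                        master_seed = config$seed,
                        subject_shift = shift,
                        rate_hz = config$rate_hz)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    files[i] <- file.path(outdir, sprintf("subject_%02d.csv", i))
    write_sensor_stream(cohort[[i]]$stream, files[i])
  }
  write_json_artifact(
    list(n_subjects = n_subjects, subject_shift = shift,
         files = basename(files)),
    file.path(outdir, "cohort.json"), config)
  log_msg("simulated %d subjects into %s", length(cohort), outdir)
  cohort
}

read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  has_label <- "label" %in% names(df)
  X <- as.matrix(df[, FEATURE_NAMES, drop = FALSE])
  list(X = X, labels = if (has_label) as.character(df$label) else NULL)
}

write_feature_csv <- function(X, path, labels = NULL, extra = NULL) {
  df <- as.data.frame(X)
  names(df) <- FEATURE_NAMES
  if (!is.null(labels)) df$label <- labels
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

pipeline_features <- function(config, paths) {
  stream <- read_sensor_stream(need_path(paths, "input", "features"),
                               rate_hz = config$rate_hz)
  stream <- separate_gravity(stream, cutoff_hz = config$gravity_cutoff_hz,
                             order = config$butter_order)
  X <- window_features(segment_windows(stream, window_s = config$window_s,
                                       overlap = config$overlap))
  labels <- attr(X, "labels")
  write_feature_csv(X, need_path(paths, "out", "features"),
                    labels = if (!all(is.na(labels))) labels)
  log_msg("extracted %d windows x %d features", nrow(X), ncol(X))
  X
}

pipeline_annotate <- function(config, paths) {
  seedset <- read_feature_csv(need_path(paths, "seed", "annotate"))
  if (is.null(seedset$labels)) stop("seed feature CSV needs a label column")
  user <- read_feature_csv(need_path(paths, "input", "annotate"))
  norm <- fit_normalizer(rbind(seedset$X, user$X))
  seeds <- seed_centroids(apply_normalizer(norm, seedset$X), seedset$labels)
  km <- kmeans_annotate(apply_normalizer(norm, user$X), seeds,
                        max_iter = config$kmeans_max_iter)
  write_feature_csv(user$X, need_path(paths, "out", "annotate"),
                    labels = km$labels)
  log_msg("annotated %d windows in %d K-Means iteration(s)",
          nrow(user$X), km$iterations)
  km
}

pipeline_filter <- function(config, paths) {
  inp <- read_feature_csv(need_path(paths, "input", "filter"))
  if (is.null(inp$labels)) stop("filter input needs a label column")
  out <- need_path(paths, "out", "filter")
  flt <- filter_outliers(inp$X, inp$labels,
                         llof_params(config$llof_k, config$llof_eps1))
  write_feature_csv(flt$kept, out, labels = flt$kept_labels)
  removed_path <- paths$removed %||%
    file.path(dirname(out), paste0("removed_", basename(out)))
  write_feature_csv(inp$X[flt$removed_index, , drop = FALSE], removed_path,
                    labels = inp$labels[flt$removed_index],
                    extra = data.frame(llof = flt$scores[flt$removed_index]))
  log_msg("kept %d / %d windows (removed %d)", nrow(flt$kept),
          nrow(inp$X), length(flt$removed_index))
  flt
}

pipeline_train <- function(config, paths) {
  stream <- read_sensor_stream(need_path(paths, "input", "train"),
                               rate_hz = config$rate_hz)
  seedset <- read_feature_csv(need_path(paths, "seed", "train"))
  if (is.null(seedset$labels)) stop("seed feature CSV needs a label column")
  clf <- train_personalized(stream, seedset$X, seedset$labels, config)
  write_classifier(clf, need_path(paths, "out", "train"))
  log_msg("trained personalized classifier (%d windows, %d removed, %d K-Means iterations)",
          clf$report$n_windows, clf$report$n_removed,
          clf$report$kmeans_iterations)
  clf
}

pipeline_classify <- function(config, paths) {
  clf <- read_classifier(need_path(paths, "model", "classify"))
  check_artifact_hash(clf$report, config, "classifier model")
  stream <- read_sensor_stream(need_path(paths, "input", "classify"),
                               rate_hz = config$rate_hz)
  pred <- classify_stream(clf, stream, config)
  utils::write.csv(pred, need_path(paths, "out", "classify"),
                   row.names = FALSE)
  log_msg("classified %d windows", nrow(pred))
  pred
}

pipeline_evaluate <- function(config, paths) {
  cohort_dir <- need_path(paths, "cohort", "evaluate")
  manifest_path <- file.path(cohort_dir, "cohort.json")
  if (!file.exists(manifest_path))
    stop("no cohort.json manifest in ", cohort_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  check_artifact_hash(manifest, config, "cohort")
  cohort <- lapply(seq_along(manifest$files), function(i)
    list(profile = subject_profile(id = i),
         stream = read_sensor_stream(file.path(cohort_dir,
                                               manifest$files[i]),
                                     rate_hz = config$rate_hz)))
  report <- loo_generic_vs_personalized(cohort, config,
                                        split_frac = config$split_frac)
  if (!is.null(paths$out))
    utils::write.csv(report$per_subject, paths$out, row.names = FALSE)
  if (!is.null(paths$out_json))
    write_json_artifact(list(summary = report$summary),
                        paths$out_json, config)
  report
}
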