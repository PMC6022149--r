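#' Personalized activity classifier
#'
#' Bundles the three per-class Gaussian models with the decision
#' thresholds and the feature normalizer fitted on the training windows.
#' Built by [train_personalized()] (full user-adaptive pipeline) or
#' [train_generic()] (plain fit on pre-labeled data).
#'
#' @param models named list of three [fit_mgd()] models (`LIA`, `MIA`,
#'   `VIA`).
#' @param normalizer the [fit_normalizer()] object applied to every
#'   incoming feature vector.
#' @param eps2 density threshold on the vigorous-class model `p3`
#'   (stored as a log-density in `log_eps2`; `eps2` is the density-scale
#'   value).
#' @param eps3 tilt-angle threshold in degrees.
#' @param report optional list of training provenance (iterations,
#'   removed windows, class sizes, config echo).
#' @return object of class `personalized_classifier`.
#' @export
personalized_classifier <- function(models, normalizer, eps2, eps3,
                                    report = list()) {
  stopifnot(setequal(names(models), ACTIVITY_CLASSES),
            all(vapply(models, inherits, logical(1L), "mgd_model")),
            inherits(normalizer, "har_normalizer"))
  if (!is.finite(eps3) || eps3 <= 0) stop("eps3 must be a positive angle")
  log_eps2 <- if (is.na(eps2)) NA_real_ else log(eps2)
  if (!is.na(eps2) && eps2 <= 0) stop("eps2 must be > 0")
  structure(list(models = models[ACTIVITY_CLASSES],
                 normalizer = normalizer,
                 eps2 = eps2, log_eps2 = log_eps2, eps3 = eps3,
                 report = report),
            class = "personalized_classifier")
}

#' @export
print.personalized_classifier <- function(x, ...) {
  sizes <- vapply(x$models, `[[`, numeric(1L), "n_train")
  cat("<personalized_classifier>\n")
  cat(sprintf("  training windows: %s\n",
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = " ")))
  cat(sprintf("  thresholds: eps2 = %.4g (density on p3), eps3 = %g deg\n",
              x$eps2, x$eps3))
  if (length(x$report))
    cat(sprintf("  pipeline: %d K-Means iteration(s), %d window(s) removed by LLOF\n",
                x$report$kmeans_iterations %||% NA_integer_,
                x$report$n_removed %||% NA_integer_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate the fall-detection thresholds
#'
#' `eps2` separates "plausibly vigorous" from "anomalously far from the
#' vigorous model": it is set to a low percentile (default the 1st) of the
#' vigorous-class density evaluated on the vigorous training windows, so
#' that almost all genuine vigorous activity stays above it while fall
#' windows — far outside the training support — fall below. `eps3` is a
#' fixed posture-change angle (default 60 degrees): a fall rotates the
#' trunk by most of 90 degrees within one window, rhythmic activity does
#' not. With fewer than 20 vigorous windows the percentile is unreliable
#' and the configured fallback density is used.
#'
#' @param via_model the fitted vigorous-class [fit_mgd()] model.
#' @param via_features normalized feature matrix of the vigorous training
#'   windows.
#' @param percentile percentile (0-100) of the training densities used
#'   for `eps2` (default 1).
#' @param eps3_deg tilt-angle threshold in degrees (default 60).
#' @param eps2_fallback density used when too few windows are available.
#' @return list with `eps2` (density scale) and `eps3` (degrees).
#' @export
calibrate_thresholds <- function(via_model, via_features, percentile = 1,
                                 eps3_deg = 60, eps2_fallback = 1e-12) {
  via_features <- as.matrix(via_features)
  if (nrow(via_features) < 20L) {
    warning("fewer than 20 vigorous-class training windows; using the ",
            "configured fallback eps2")
    return(list(eps2 = eps2_fallback, eps3 = eps3_deg))
  }
  logp <- mgd_log_density(via_model, via_features)
  log_eps2 <- as.numeric(
    stats::quantile(logp, probs = percentile / 100, type = 7, names = FALSE))
  list(eps2 = exp(log_eps2), eps3 = eps3_deg)
}

#' Classify one feature window
#'
#' The raw 13-feature vector is normalized with the classifier's stored
#' normalizer and scored under the three class densities (in log space).
#' The winning class index decides: light or moderate directly; a
#' vigorous winner is reported as a fall only when both fall conditions
#' hold — density at or below `eps2` (the window does not look like
#' trained vigorous activity) and tilt angle at or above `eps3` (the
#' posture changed like a fall). The tilt-angle test uses the raw,
#' un-normalized 13th feature (degrees). Density ties break toward the
#' lower-intensity class.
#'
#' @param clf a [personalized_classifier()].
#' @param fv raw 13-feature vector (or matrix of rows) as produced by
#'   [extract_features()].
#' @return character label(s) in `{LIA, MIA, VIA, Fall}`.
#' @export
classify_window <- function(clf, fv) {
  stopifnot(inherits(clf, "personalized_classifier"))
  if (is.null(dim(fv))) fv <- matrix(fv, nrow = 1L,
                                     dimnames = list(NULL, FEATURE_NAMES))
  fv <- as.matrix(fv)
  ta <- fv[, 13L]
  z <- apply_normalizer(clf$normalizer, fv)
  logp <- vapply(clf$models, mgd_log_density, numeric(nrow(z)), x = z)
  if (nrow(z) == 1L) logp <- matrix(logp, nrow = 1L)
  winner <- apply(logp, 1L, which.max)  # ties -> lowest index (LIA first)
  out <- ACTIVITY_CLASSES[winner]
  is_fall <- winner == 3L &
    logp[, 3L] <= clf$log_eps2 &
    ta >= clf$eps3
  out[is_fall] <- "Fall"
  out
}

#' Fit a classifier directly on a labeled feature set
#'
#' The non-adaptive ("generic") route: no clustering and no outlier
#' filtering, just a normalizer, three Gaussians and threshold
#' calibration on pre-labeled windows — typically pooled from other
#' subjects in the leave-one-out protocol.
#'
#' @param features raw feature matrix (rows = windows, 13 columns).
#' @param labels class label per row; must cover LIA, MIA and VIA.
#' @param config a [har_config()].
#' @return a [personalized_classifier()] (fitted generically).
#' @export
train_generic <- function(features, labels, config = har_config()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  keep <- labels %in% ACTIVITY_CLASSES
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  missing <- setdiff(ACTIVITY_CLASSES, unique(labels))
  if (length(missing))
    stop("labeled data is missing class(es): ",
         paste(missing, collapse = ", "))
  norm <- fit_normalizer(features)
  Z <- apply_normalizer(norm, features)
  models <- lapply(ACTIVITY_CLASSES, function(cl)
    fit_mgd(Z[labels == cl, , drop = FALSE], label = cl))
  names(models) <- ACTIVITY_CLASSES
  thr <- calibrate_thresholds(models$VIA,
                              Z[labels == "VIA", , drop = FALSE],
                              percentile = config$eps2_percentile,
                              eps3_deg = config$eps3_deg)
  personalized_classifier(models, norm, thr$eps2, thr$eps3,
                          report = list(mode = "generic",
                                        n_windows = nrow(features)))
}

#' Train a personalized classifier from an unlabeled user stream
#'
#' The full user-adaptive pipeline: gravity separation, windowing and
#' feature extraction on the user's own (fall-free) recording; automatic
#' annotation by K-Means seeded at the labeled class centroids of the
#' pre-collected dataset; removal of low-confidence windows by the
#' label-restricted local outlier factor; per-class Gaussian fits and
#' fall-threshold calibration on what remains.
#'
#' Two normalizers are used on purpose: the seeds and the user's windows
#' are scaled together (fit on their union) so that seeded distances are
#' meaningful, and the final models are fitted under a normalizer refit
#' on the user's kept windows alone, which is the one stored in the
#' classifier.
#'
#' @param stream the user's calibrated, fall-free [har_stream()].
#' @param seed_features pre-labeled feature matrix (raw scale) from other
#'   users.
#' @param seed_labels class label per row of `seed_features`.
#' @param config a [har_config()].
#' @return a [personalized_classifier()]; its `report` lists K-Means
#'   iterations, LLOF removals and per-class training sizes.
#' @export
train_personalized <- function(stream, seed_features, seed_labels,
                               config = har_config()) {
  stopifnot(inherits(stream, "har_stream"))
  seed_features <- as.matrix(seed_features)
  seed_labels <- as.character(seed_labels)
  keep <- seed_labels %in% ACTIVITY_CLASSES
  seed_features <- seed_features[keep, , drop = FALSE]
  seed_labels <- seed_labels[keep]

  stream <- separate_gravity(stream, cutoff_hz = config$gravity_cutoff_hz,
                             order = config$butter_order)
  windows <- segment_windows(stream, window_s = config$window_s,
                             overlap = config$overlap)
  X <- window_features(windows)

  # shared scale for seeding + annotation
  norm_union <- fit_normalizer(rbind(seed_features, X))
  seeds <- seed_centroids(apply_normalizer(norm_union, seed_features),
                          seed_labels)
  km <- kmeans_annotate(apply_normalizer(norm_union, X), seeds,
                        max_iter = config$kmeans_max_iter)

  flt <- filter_outliers(apply_normalizer(norm_union, X), km$labels,
                         llof_params(config$llof_k, config$llof_eps1))
  kept_raw <- X[flt$kept_index, , drop = FALSE]
  kept_labels <- km$labels[flt$kept_index]

  sizes <- table(factor(kept_labels, levels = ACTIVITY_CLASSES))
  empty <- names(sizes)[sizes < 2L]
  if (length(empty))
    stop("class(es) ", paste(empty, collapse = ", "),
         " have fewer than 2 windows after LLOF filtering")

  # user-only scale for the final models
  norm_user <- fit_normalizer(kept_raw)
  Z <- apply_normalizer(norm_user, kept_raw)
  models <- lapply(ACTIVITY_CLASSES, function(cl)
    fit_mgd(Z[kept_labels == cl, , drop = FALSE], label = cl))
  names(models) <- ACTIVITY_CLASSES
  thr <- calibrate_thresholds(models$VIA,
                              Z[kept_labels == "VIA", , drop = FALSE],
                              percentile = config$eps2_percentile,
                              eps3_deg = config$eps3_deg)

  personalized_classifier(
    models, norm_user, thr$eps2, thr$eps3,
    report = list(mode = "personalized",
                  kmeans_iterations = km$iterations,
                  kmeans_converged = km$converged,
                  n_windows = nrow(X),
                  n_removed = length(flt$removed_index),
                  class_sizes = as.list(sizes),
                  config_hash = config_hash(config)))
}

#' Classify every window of a stream
#'
#' Convenience wrapper: gravity separation, windowing, feature extraction
#' and per-window classification in one call.
#'
#' @param clf a [personalized_classifier()].
#' @param stream a calibrated [har_stream()].
#' @param config a [har_config()].
#' @return data frame with one row per window: `window`, `start`
#'   (0-based sample index), `predicted`, and `truth` (majority window
#'   label, `NA` without a label track).
#' @export
classify_stream <- function(clf, stream, config = har_config()) {
  stream <- separate_gravity(stream, cutoff_hz = config$gravity_cutoff_hz,
                             order = config$butter_order)
  windows <- segment_windows(stream, window_s = config$window_s,
                             overlap = config$overlap)
  X <- window_features(windows)
  data.frame(window = seq_len(nrow(X)),
             start = attr(X, "start"),
             predicted = classify_window(clf, X),
             truth = attr(X, "labels"),
             stringsAsFactors = FALSE)
}

#' Serialize a classifier to JSON
#'
#' Mean vectors, covariances (row-major), thresholds, normalizer and the
#' training report are written as a single JSON document readable by
#' [read_classifier()].
#'
#' @param clf a [personalized_classifier()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "personalized_classifier"))
  doc <- list(
    format = "harfall-classifier-v1",
    models = lapply(clf$models, function(m)
      list(label = m$label, mu = unname(m$mu),
           sigma = unname(m$sigma), n_train = m$n_train)),
    eps2 = clf$eps2, eps3 = clf$eps3,
    normalizer = list(min = unname(clf$normalizer$min),
                      range = unname(clf$normalizer$range)),
    report = clf$report)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a classifier back from JSON
#'
#' @param path a file written by [write_classifier()].
#' @return a [personalized_classifier()].
#' @export
read_classifier <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "harfall-classifier-v1"))
    stop("not a harfall classifier file: ", path)
  models <- lapply(names(doc$models), function(cl) {
    m <- doc$models[[cl]]
    sigma <- matrix(unlist(m$sigma), nrow = length(m$mu), byrow = FALSE)
    R <- chol((sigma + t(sigma)) / 2)
    structure(list(mu = stats::setNames(as.numeric(m$mu), FEATURE_NAMES),
                   sigma = sigma, chol = R,
                   log_det = 2 * sum(log(diag(R))),
                   n_dim = length(m$mu), n_train = m$n_train,
                   label = m$label),
              class = "mgd_model")
  })
  names(models) <- names(doc$models)
  norm <- structure(list(min = stats::setNames(as.numeric(doc$normalizer$min),
                                               FEATURE_NAMES),
                         range = stats::setNames(as.numeric(doc$normalizer$range),
                                                 FEATURE_NAMES),
                         method = "minmax"),
                    class = "har_normalizer")
  personalized_classifier(models, norm, doc$eps2, doc$eps3,
                          report = doc$report)
}
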