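CHANNELS <- c("ax", "ay", "az", "wx", "wy", "wz")
ACTIVITY_CLASSES <- c("LIA", "MIA", "VIA")
ALL_CLASSES <- c("LIA", "MIA", "VIA", "Fall")

#' Construct a six-axis inertial stream
#'
#' A `har_stream` holds one continuous recording from a waist-worn
#' six-axis inertial unit: tri-axial acceleration (`ax`, `ay`, `az`, in g)
#' and tri-axial angular velocity (`wx`, `wy`, `wz`, in deg/s) sampled at a
#' fixed rate, plus an optional per-sample ground-truth activity label
#' track used only for evaluation.
#'
#' @param samples numeric matrix with 6 columns (ax, ay, az, wx, wy, wz),
#'   one row per sample; all values must be finite.
#' @param rate_hz sampling frequency in Hz (> 0); 50 for the supported
#'   protocol.
#' @param labels optional character vector of per-sample activity labels,
#'   same length as `nrow(samples)`.
#' @return an object of class `har_stream` with elements `samples`,
#'   `rate_hz`, `labels`, and (after [separate_gravity()]) `gravity` and
#'   `body`.
#' @export
har_stream <- function(samples, rate_hz = 50, labels = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 6L)
    stop("samples must have exactly 6 columns (ax, ay, az, wx, wy, wz)")
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("all sensor values must be finite numerics")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  colnames(samples) <- CHANNELS
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(samples))
      stop("labels must have one entry per sample (",
           length(labels), " labels vs ", nrow(samples), " samples)")
  }
  structure(
    list(samples = samples, rate_hz = rate_hz, labels = labels,
         gravity = NULL, body = NULL),
    class = "har_stream"
  )
}

#' @export
print.har_stream <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<har_stream> %d samples @ %g Hz (%.1f s)%s%s\n",
              n, x$rate_hz, n / x$rate_hz,
              if (!is.null(x$labels)) ", labelled" else "",
              if (!is.null(x$body)) ", gravity-separated" else ""))
  invisible(x)
}

#' @export
length.har_stream <- function(x) nrow(x$samples)

#' Read a raw sensor stream from CSV
#'
#' Expects one sample per row in fixed column order
#' `ax,ay,az,wx,wy,wz[,label]`. A header row is optional and auto-detected
#' (a non-numeric first field in the first row). Malformed rows abort with
#' the offending line number.
#'
#' @param path path to a comma-separated file.
#' @param rate_hz sampling frequency of the recording (Hz).
#' @return a [har_stream()] in file order, with the label track attached
#'   when a seventh column is present.
#' @export
read_sensor_stream <- function(path, rate_hz = 50) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty sensor file: ", path)

  fields <- strsplit(lines, ",", fixed = TRUE)
  first <- suppressWarnings(as.numeric(trimws(fields[[1L]][1L])))
  has_header <- is.na(first)
  offset <- if (has_header) 1L else 0L
  if (has_header) fields <- fields[-1L]
  if (length(fields) == 0L) stop("no data rows in ", path)

  ncols <- lengths(fields)
  bad <- which(ncols < 6L | ncols > 7L)
  if (length(bad))
    stop("line ", bad[1L] + offset, ": expected 6 or 7 comma-separated ",
         "columns, found ", ncols[bad[1L]])
  has_label <- ncols[1L] == 7L
  if (any(ncols != ncols[1L])) {
    bad <- which(ncols != ncols[1L])[1L]
    stop("line ", bad + offset, ": inconsistent column count")
  }

  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(trimws(f[1:6])), numeric(6L)))
  badcell <- which(colSums(is.na(vals)) > 0L)
  if (length(badcell))
    stop("line ", badcell[1L] + offset, ": non-numeric sensor value")

  labels <- if (has_label)
    vapply(fields, function(f) trimws(f[7L]), character(1L)) else NULL
  har_stream(t(vals), rate_hz = rate_hz, labels = labels)
}

#' Write a sensor stream to CSV
#'
#' Inverse of [read_sensor_stream()]: fixed column order with a header
#' row, label column appended when the stream carries one. Finite values
#' round-trip bit-identically (full precision, `%.17g`).
#'
#' @param stream a [har_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_stream <- function(stream, path) {
  stopifnot(inherits(stream, "har_stream"))
  num <- apply(stream$samples, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  header <- paste(CHANNELS, collapse = ",")
  if (!is.null(stream$labels)) {
    num <- paste(num, stream$labels, sep = ",")
    header <- paste0(header, ",label")
  }
  writeLines(c(header, num), path)
  invisible(path)
}

#' Sensitivity and zero-drift calibration parameters
#'
#' Raw sensor counts are mapped to physical units channel by channel as
#' `x = raw / k + b`, with one sensitivity coefficient `k` and one
#' zero-drift offset `b` per channel. Offsets default to 0: for a
#' consumer-grade IMU the drift contribution is negligible relative to
#' activity dynamics. The defaults `k = 1, b = 0` leave data already in
#' physical units untouched.
#'
#' @param k numeric vector of 6 positive sensitivities, order
#'   ax, ay, az, wx, wy, wz.
#' @param b numeric vector of 6 zero-drift offsets (same order).
#' @return an object of class `calibration_params`.
#' @export
calibration_params <- function(k = rep(1, 6), b = rep(0, 6)) {
  k <- as.numeric(k); b <- as.numeric(b)
  if (length(k) != 6L || length(b) != 6L)
    stop("k and b must each have 6 entries")
  if (any(!is.finite(k)) || any(k <= 0))
    stop("all sensitivity coefficients must be positive and finite")
  if (any(!is.finite(b))) stop("zero-drift offsets must be finite")
  names(k) <- names(b) <- CHANNELS
  structure(list(k = k, b = b), class = "calibration_params")
}

#' Calibrate a raw stream
#'
#' Applies `x = raw / k + b` per channel. Length, ordering, labels and
#' sampling rate are preserved.
#'
#' @param stream a [har_stream()] of raw values.
#' @param params a [calibration_params()].
#' @return a calibrated [har_stream()].
#' @export
calibrate <- function(stream, params = calibration_params()) {
  stopifnot(inherits(stream, "har_stream"),
            inherits(params, "calibration_params"))
  out <- sweep(stream$samples, 2L, params$k, "/")
  out <- sweep(out, 2L, params$b, "+")
  har_stream(out, rate_hz = stream$rate_hz, labels = stream$labels)
}
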