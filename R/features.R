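FEATURE_NAMES <- c("a_mean", "a_std", "a_energy", "a_mcr", "a_max", "a_min",
                   "w_mean", "w_std", "w_energy", "w_mcr", "w_max", "w_min",
                   "tilt_angle")

#' Euclidean magnitude of a tri-axial signal
#'
#' Collapses the three axes into one orientation-free intensity track,
#' `sqrt(x^2 + y^2 + z^2)`.
#'
#' @param xyz numeric vector of length 3, or an n-by-3 matrix.
#' @return a scalar, or a length-n vector for matrix input.
#' @export
magnitude <- function(xyz) {
  if (is.matrix(xyz)) return(sqrt(rowSums(xyz^2)))
  sqrt(sum(xyz^2))
}

#' Tilt angle of a window
#'
#' Norm of the angular displacement about the x (transverse) and z
#' (sagittal) axes accumulated over one window:
#' `TA = sqrt((sum wx dt)^2 + (sum wz dt)^2)` with rectangular
#' integration, `dt = 1/rate_hz`. Integration restarts at every window.
#' A fall rotates the trunk by roughly 70-90 degrees within a window,
#' while rhythmic gait oscillations integrate to nearly zero, so TA is
#' the posture-change channel of the fall rule.
#'
#' @param gyro L-by-3 gyroscope block (deg/s), columns wx, wy, wz.
#' @param rate_hz sampling frequency (Hz).
#' @return tilt angle in degrees (non-negative).
#' @export
tilt_angle <- function(gyro, rate_hz) {
  gyro <- as.matrix(gyro)
  dt <- 1 / rate_hz
  sqrt(sum(gyro[, 1L] * dt)^2 + sum(gyro[, 3L] * dt)^2)
}

# Six summary statistics of one magnitude track. Population standard
# deviation (divisor L); energy is the mean square; mean-crossing rate is
# the fraction of the L-1 consecutive pairs that straddle the track mean.
magnitude_stats <- function(s) {
  L <- length(s)
  m <- mean(s)
  centered <- s - m
  mcr <- if (L > 1L) {
    sgn <- sign(centered)
    sum(sgn[-1L] * sgn[-L] < 0) / (L - 1L)
  } else 0
  c(mean = m,
    std = sqrt(sum(centered^2) / L),
    energy = sum(s^2) / L,
    mcr = mcr,
    max = max(s),
    min = min(s))
}

#' Extract the 13 time-domain features of one window
#'
#' Mean, standard deviation, energy, mean-crossing rate, maximum and
#' minimum of the body-acceleration magnitude and of the angular-velocity
#' magnitude (12 values), plus the window tilt angle as the 13th.
#' Acceleration features use the gravity-removed body component so that
#' they measure movement intensity rather than the constant 1 g.
#'
#' @param window one element of a [segment_windows()] result.
#' @param rate_hz sampling frequency (Hz); defaults to 50.
#' @return named numeric vector of length 13 in the order
#'   `a_mean, a_std, a_energy, a_mcr, a_max, a_min, w_mean, ..., w_min,
#'   tilt_angle`.
#' @export
extract_features <- function(window, rate_hz = 50) {
  a <- magnitude(window$body)
  w <- magnitude(window$block[, 4:6, drop = FALSE])
  fv <- c(magnitude_stats(a), magnitude_stats(w),
          tilt_angle(window$block[, 4:6, drop = FALSE], rate_hz))
  names(fv) <- FEATURE_NAMES
  fv
}

#' Feature matrix for a whole window list
#'
#' @param windows a `har_windows` list from [segment_windows()].
#' @return numeric matrix (windows-by-13) with feature names as columns
#'   and attributes `labels` (majority window labels, possibly `NA`) and
#'   `start` (0-based window starts).
#' @export
window_features <- function(windows) {
  stopifnot(inherits(windows, "har_windows"))
  rate <- attr(windows, "rate_hz")
  X <- t(vapply(windows, extract_features, numeric(13L), rate_hz = rate))
  attr(X, "labels") <- vapply(windows, `[[`, character(1L), "label")
  attr(X, "start") <- vapply(windows, `[[`, numeric(1L), "start")
  X
}

#' Fit a min-max feature normalizer
#'
#' Per-feature min-max scaling to `[0, 1]`, learned on training data only
#' and stored inside the classifier so exactly the same mapping is applied
#' at test time (no leakage). A feature that is constant across the
#' training set gets unit scale, so it maps to 0 everywhere.
#'
#' @param X training feature matrix (rows = windows, 13 columns).
#' @return an object of class `har_normalizer` with fields `min` and
#'   `range`.
#' @export
fit_normalizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training vectors to fit")
  lo <- apply(X, 2L, min)
  rg <- apply(X, 2L, max) - lo
  rg[rg <= 0] <- 1
  structure(list(min = lo, range = rg, method = "minmax"),
            class = "har_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param normalizer a [fit_normalizer()] result.
#' @param X feature vector or matrix on the raw feature scale.
#' @return normalized values; test-time values outside the training range
#'   are not clamped and may fall outside `[0, 1]`.
#' @export
apply_normalizer <- function(normalizer, X) {
  stopifnot(inherits(normalizer, "har_normalizer"))
  if (is.null(dim(X))) {
    (X - normalizer$min) / normalizer$range
  } else {
    sweep(sweep(as.matrix(X), 2L, normalizer$min, "-"),
          2L, normalizer$range, "/")
  }
}
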