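# Steady-state initial conditions for a direct-form II transposed IIR
# filter: the state that makes a constant input produce a constant output
# from the first sample on.
lfilter_zi <- function(b, a) {
  n <- length(a)
  if (length(b) != n) stop("b and a must have equal length")
  companion_t <- rbind(-a[-1L], cbind(diag(n - 2L), 0))
  rhs <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(companion_t), rhs)
}

iir_filter <- function(b, a, x, zi) {
  n <- length(x); nb <- length(b)
  y <- numeric(n); z <- c(zi, 0)
  for (i in seq_len(n)) {
    y[i] <- b[1L] * x[i] + z[1L]
    for (j in seq_len(nb - 1L))
      z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * y[i]
  }
  y
}

# Zero-phase filtering: forward and backward passes with steady-state
# initial conditions, over an odd-reflection extension of the signal so
# that both ends see a continuation rather than a step. A constant signal
# passes through exactly (up to rounding).
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 10L * 3L * (length(a) - 1L))
  zi <- lfilter_zi(b, a)
  xe <- c(2 * x[1L] - x[(pad + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  y <- iir_filter(b, a, xe, zi * xe[1L])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

#' Separate gravity from body acceleration
#'
#' The three acceleration channels are low-pass filtered with a zero-phase
#' (forward-backward) Butterworth filter; the low-frequency component is
#' the gravity estimate and the residual is body acceleration. Gravity has
#' only very low frequency content, so a 0.3-Hz cutoff keeps posture while
#' rejecting movement. Gyroscope channels pass through untouched.
#'
#' @param stream a calibrated [har_stream()].
#' @param cutoff_hz low-pass cutoff in Hz (default 0.3); must be below the
#'   Nyquist frequency.
#' @param order Butterworth filter order (default 3).
#' @return the input stream with matrices `gravity` and `body` (each
#'   n-by-3, columns ax, ay, az) attached; `gravity + body` reconstructs
#'   the acceleration channels exactly.
#' @export
separate_gravity <- function(stream, cutoff_hz = 0.3, order = 3) {
  stopifnot(inherits(stream, "har_stream"))
  if (cutoff_hz >= stream$rate_hz / 2)
    stop("cutoff_hz (", cutoff_hz, ") must be below the Nyquist frequency (",
         stream$rate_hz / 2, " Hz)")
  n <- nrow(stream$samples)
  if (n < 3L * order) stop("stream too short for filter warm-up")
  bf <- signal::butter(order, cutoff_hz / (stream$rate_hz / 2), type = "low")
  acc <- stream$samples[, 1:3, drop = FALSE]
  gravity <- apply(acc, 2L, function(x) zero_phase_filter(bf$b, bf$a, x))
  colnames(gravity) <- CHANNELS[1:3]
  stream$gravity <- gravity
  stream$body <- acc - gravity
  stream
}

#' Segment a stream into overlapping windows
#'
#' Windows of `window_s` seconds with fractional `overlap` (0.5 means a
#' hop of half a window). Only complete windows are emitted; a trailing
#' fragment is dropped. At the 50-Hz / 1-s / 50% defaults window k
#' (1-based) starts at sample index 25*(k-1) (0-based) and holds 50
#' samples, so a 300-ms fall transient is always fully contained in at
#' least one window.
#'
#' If the stream carries a label track, each window receives the majority
#' label of its samples; ties are broken toward the label of the window's
#' last sample (fall transients sit at the end of the windows that
#' matter).
#'
#' @param stream a [har_stream()], normally after [separate_gravity()].
#' @param window_s window duration in seconds (default 1).
#' @param overlap fraction of a window shared with its predecessor, in
#'   `[0, 1)` (default 0.5).
#' @return a list of class `har_windows`; each element has `index`
#'   (1-based), `start` (0-based sample index), `block` (L-by-6 sample
#'   matrix), `body` (L-by-3 body-acceleration matrix; raw acceleration if
#'   gravity was not separated) and `label` (majority label or `NA`).
#' @export
segment_windows <- function(stream, window_s = 1, overlap = 0.5) {
  stopifnot(inherits(stream, "har_stream"))
  if (overlap < 0 || overlap >= 1)
    stop("overlap must be in [0, 1); got ", overlap)
  L <- round(window_s * stream$rate_hz)
  hop <- round(L * (1 - overlap))
  if (hop < 1L) stop("window hop is zero; decrease overlap")
  n <- nrow(stream$samples)
  if (n < L)
    stop("stream shorter than one window (", n, " < ", L, " samples)")
  body_all <- if (!is.null(stream$body)) stream$body
              else stream$samples[, 1:3, drop = FALSE]
  m <- floor((n - L) / hop) + 1L
  windows <- vector("list", m)
  for (k in seq_len(m)) {
    start <- hop * (k - 1L)
    idx <- (start + 1L):(start + L)
    lab <- NA_character_
    if (!is.null(stream$labels)) {
      labs <- stream$labels[idx]
      counts <- table(labs)
      top <- names(counts)[counts == max(counts)]
      lab <- if (labs[L] %in% top) labs[L] else top[1L]
    }
    windows[[k]] <- list(
      index = k, start = start,
      block = stream$samples[idx, , drop = FALSE],
      body = body_all[idx, , drop = FALSE],
      label = lab)
  }
  structure(windows, class = "har_windows",
            window_length = L, hop = hop, rate_hz = stream$rate_hz)
}

#' @export
print.har_windows <- function(x, ...) {
  cat(sprintf("<har_windows> %d windows of %d samples, hop %d @ %g Hz\n",
              length(x), attr(x, "window_length"), attr(x, "hop"),
              attr(x, "rate_hz")))
  invisible(x)
}
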