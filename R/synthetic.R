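# Base signal parameters of the simulator. Amplitudes in g (acceleration)
# and deg/s (gyro); frequencies in Hz. The signal model is deliberately
# simple -- gravity plus class-specific sinusoids, slow AR(1) variability,
# noise and scripted transients -- because the pipeline needs statistical
# structure (class separation, subject shift, fall geometry), not
# biomechanical realism.
SIM_BASE <- list(
  LIA = list(acc_amp = 0.00, gyro_amp = 0,  freq = 0,   acc_noise = 0.02,
             gyro_noise = 1.5, fidget_acc = 0.05, fidget_gyro = 4),
  MIA = list(acc_amp = 0.25, gyro_amp = 25, freq = 2.0, acc_noise = 0.03,
             gyro_noise = 2.0),
  VIA = list(acc_amp = 0.80, gyro_amp = 70, freq = 3.1, acc_noise = 0.05,
             gyro_noise = 3.0),
  fall = list(transient_s = 0.3, settle_s = 0.7, post_s = 0.5,
              spike_down_g = 2.5, spike_up_g = 1.2,
              tilt_deg = 90, amp_mod = 0.1, fidget_tau_s = 1.0)
)

#' Per-subject signal profile
#'
#' Captures the between-person distribution shift the adaptive pipeline
#' exists for: each subject scales the class signal amplitudes, shifts
#' the gait frequencies, wears the sensor at a slightly different
#' baseline orientation, and has their own noise level.
#'
#' @param id subject identifier.
#' @param amp_mult named multipliers (`LIA`, `MIA`, `VIA`) applied to the
#'   class amplitude and noise scales; must be positive.
#' @param gyro_mult multiplier on the trunk-rotation amplitude of gait
#'   (how much the subject rotates while moving, independent of movement
#'   vigor); must be positive.
#' @param orient_deg baseline sensor tilt about the y axis, degrees.
#' @param freq_offset_hz named gait-frequency offsets (`MIA`, `VIA`), Hz.
#' @param noise_mult global noise multiplier (>= 0).
#' @param seed RNG seed for this subject's stream.
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(id = 1L,
                            amp_mult = c(LIA = 1, MIA = 1, VIA = 1),
                            gyro_mult = 1,
                            orient_deg = 0,
                            freq_offset_hz = c(MIA = 0, VIA = 0),
                            noise_mult = 1,
                            seed = 1L) {
  if (any(amp_mult <= 0)) stop("amplitude multipliers must be positive")
  if (gyro_mult <= 0) stop("gyro_mult must be positive")
  if (noise_mult < 0) stop("noise_mult must be >= 0")
  structure(list(id = id, amp_mult = amp_mult, gyro_mult = gyro_mult,
                 orient_deg = orient_deg,
                 freq_offset_hz = freq_offset_hz, noise_mult = noise_mult,
                 seed = as.integer(seed)),
            class = "subject_profile")
}

#' Session script
#'
#' An ordered list of activity segments. A `Fall` entry (at least 3 s)
#' models a fall during vigorous activity: vigorous signal, then a 2-s
#' fall event — a 300-ms impact transient, 0.7 s down, a 300-ms recovery
#' transient and 0.7 s regaining balance — then vigorous signal again.
#' The full 2-s event is labelled `Fall`, the flanks `VIA`. Keep
#' durations at multiples of 0.5 s so segment boundaries land on the
#' default window grid.
#'
#' @param activity character vector over `{LIA, MIA, VIA, Fall}`.
#' @param duration_s positive durations in seconds.
#' @return a data frame of class `session_script`.
#' @export
session_script <- function(activity, duration_s) {
  if (length(activity) != length(duration_s))
    stop("activity and duration_s lengths differ")
  if (!all(activity %in% ALL_CLASSES))
    stop("unknown activity; use LIA, MIA, VIA or Fall")
  if (any(duration_s <= 0)) stop("durations must be positive")
  if (any(activity == "Fall" & duration_s < 3))
    stop("Fall segments need at least 3 s (vigorous flank + 2-s fall event)")
  structure(data.frame(activity = activity, duration_s = duration_s,
                       stringsAsFactors = FALSE),
            class = c("session_script", "data.frame"))
}

#' Default session script
#'
#' 187.5 s per subject: 50 s of each intensity class for training, then a
#' 37.5-s test tail (8 s per class plus three 4.5-s fall events), giving
#' the 4:1 train/test split at the 80% mark with falls confined to the
#' test portion — falls are never part of training data.
#'
#' @return a [session_script()].
#' @export
default_session_script <- function() {
  session_script(
    activity = c("LIA", "MIA", "VIA",
                 "LIA", "MIA", "VIA", "Fall", "Fall", "Fall"),
    duration_s = c(50, 50, 50, 8, 8, 8, 4.5, 4.5, 4.5))
}

# gravity vector (in g) for trunk tilt `tilt_deg` about the x axis, with
# a fixed baseline tilt `orient_deg` about y. Standing: ~(sin b, 0, cos b).
gravity_vec <- function(orient_deg, tilt_deg) {
  b <- orient_deg * pi / 180
  phi <- tilt_deg * pi / 180
  g0 <- c(sin(b), 0, cos(b))
  c(g0[1L],
    g0[2L] * cos(phi) - g0[3L] * sin(phi),
    g0[2L] * sin(phi) + g0[3L] * cos(phi))
}

# Smooth AR(1) track with stationary sd `sd` and correlation time `tau_s`;
# models slow posture drift / fidgeting / effort modulation.
ar1_track <- function(n, sd, tau_s, rate_hz) {
  if (sd <= 0) return(numeric(n))
  phi <- exp(-1 / (tau_s * rate_hz))
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# gravity matrix along a tilt path (degrees about x)
gravity_path <- function(orient_deg, tilt_path) {
  t(vapply(tilt_path, function(a) gravity_vec(orient_deg, a), numeric(3L)))
}

#' Simulate one subject's six-axis stream
#'
#' Light activity is the gravity vector plus slow fidget drift and
#' low-variance noise; moderate and vigorous activity add gait-like
#' sinusoids with slowly varying effort on the acceleration and gyro
#' channels (moderate ~2 Hz moderate amplitude, vigorous ~3 Hz large
#' amplitude). A `Fall` segment models a fall in the middle of vigorous
#' activity, keeping the gravity vector continuous through a scripted
#' tilt path: a 300-ms fall transient (half-sine gyro pulse about x
#' integrating to 90 degrees plus a 2.5-g impact spike), 0.7 s down, a
#' 300-ms recovery transient back upright (with a smaller push-off
#' spike), and 0.7 s regaining balance — 2 s labelled `Fall`, flanked by
#' `VIA` signal. Fully reproducible from the profile seed.
#'
#' @param profile a [subject_profile()].
#' @param script a [session_script()].
#' @param rate_hz sampling frequency (default 50).
#' @return a labelled [har_stream()].
#' @export
simulate_subject <- function(profile, script = default_session_script(),
                             rate_hz = 50) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(script, "session_script"))
  set.seed(profile$seed)
  dt <- 1 / rate_hz
  fall <- SIM_BASE$fall
  lia <- SIM_BASE$LIA
  seg_samples <- list()
  seg_labels <- list()

  still_block <- function(n, tilt_path) {
    # still posture (standing or lying) with fidget + white noise
    amp <- profile$amp_mult[["LIA"]]
    acc <- gravity_path(profile$orient_deg, tilt_path)
    for (j in 1:3)
      acc[, j] <- acc[, j] +
        ar1_track(n, lia$fidget_acc * amp * profile$noise_mult,
                  fall$fidget_tau_s, rate_hz) +
        stats::rnorm(n, sd = lia$acc_noise * amp * profile$noise_mult)
    gyr <- matrix(0, n, 3L)
    for (j in 1:3)
      gyr[, j] <- ar1_track(n, lia$fidget_gyro * profile$noise_mult,
                            fall$fidget_tau_s, rate_hz) +
        stats::rnorm(n, sd = lia$gyro_noise * profile$noise_mult)
    list(acc = acc, gyr = gyr)
  }

  active_block <- function(act, n) {
    # gait-like oscillation with slowly varying effort
    p <- SIM_BASE[[act]]
    amp <- profile$amp_mult[[act]]
    off <- if (act %in% names(profile$freq_offset_hz))
      profile$freq_offset_hz[[act]] else 0
    f <- p$freq + off
    t <- (seq_len(n) - 1L) * dt
    effort <- 1 + ar1_track(n, fall$amp_mod, 2 * fall$fidget_tau_s, rate_hz)
    wave <- effort * sin(2 * pi * f * t)
    wave90 <- effort * sin(2 * pi * f * t + pi / 2)
    g <- gravity_vec(profile$orient_deg, 0)
    acc <- matrix(rep(g, each = n), ncol = 3L)
    acc[, 1L] <- acc[, 1L] + 0.5 * p$acc_amp * amp * wave90
    acc[, 3L] <- acc[, 3L] + p$acc_amp * amp * wave
    gyr <- matrix(0, n, 3L)
    gyr[, 1L] <- p$gyro_amp * amp * profile$gyro_mult * wave
    gyr[, 3L] <- 0.6 * p$gyro_amp * amp * profile$gyro_mult * wave90
    acc <- acc + matrix(stats::rnorm(n * 3L,
                                     sd = p$acc_noise * amp * profile$noise_mult),
                        n, 3L)
    gyr <- gyr + matrix(stats::rnorm(n * 3L,
                                     sd = p$gyro_noise * profile$noise_mult),
                        n, 3L)
    list(acc = acc, gyr = gyr)
  }

  fall_event <- function() {
    # 2-s event: impact pulse, 0.7 s down, recovery pulse, 0.7 s upright
    n_tr <- round(fall$transient_s * rate_hz)
    n_settle <- round(fall$settle_s * rate_hz)
    n_ev <- 2L * (n_tr + n_settle)
    shape <- sin(pi * (seq_len(n_tr) - 0.5) / n_tr)
    pulse <- fall$tilt_deg / (dt * sum(shape)) * shape  # integrates to 90 deg
    wx <- c(pulse, rep(0, n_settle), -pulse, rep(0, n_settle))
    tilt_path <- cumsum(wx) * dt
    blk <- still_block(n_ev, tilt_path)
    acc <- blk$acc
    gyr <- blk$gyr
    gyr[, 1L] <- gyr[, 1L] + wx
    spike <- function(peak) peak * shape^2
    i_down <- seq_len(n_tr)
    i_up <- n_tr + n_settle + seq_len(n_tr)
    acc[i_down, 2L] <- acc[i_down, 2L] - 0.7 * spike(fall$spike_down_g)
    acc[i_down, 3L] <- acc[i_down, 3L] + spike(fall$spike_down_g)
    acc[i_up, 2L] <- acc[i_up, 2L] + 0.7 * spike(fall$spike_up_g)
    acc[i_up, 3L] <- acc[i_up, 3L] + spike(fall$spike_up_g)
    list(acc = acc, gyr = gyr, n = n_ev)
  }

  for (row in seq_len(nrow(script))) {
    act <- script$activity[row]
    n <- round(script$duration_s[row] * rate_hz)
    if (act == "LIA") {
      blk <- still_block(n, rep(0, n))
      seg_samples[[length(seg_samples) + 1L]] <- cbind(blk$acc, blk$gyr)
      seg_labels[[length(seg_labels) + 1L]] <- rep("LIA", n)
    } else if (act %in% c("MIA", "VIA")) {
      blk <- active_block(act, n)
      seg_samples[[length(seg_samples) + 1L]] <- cbind(blk$acc, blk$gyr)
      seg_labels[[length(seg_labels) + 1L]] <- rep(act, n)
    } else {  # Fall during vigorous activity
      ev <- fall_event()
      n_post <- round(fall$post_s * rate_hz)
      n_pre <- n - ev$n - n_post
      if (n_pre < 1L) stop("Fall segment too short")
      pre <- active_block("VIA", n_pre)
      post <- active_block("VIA", n_post)
      seg_samples[[length(seg_samples) + 1L]] <-
        rbind(cbind(pre$acc, pre$gyr),
              cbind(ev$acc, ev$gyr),
              cbind(post$acc, post$gyr))
      seg_labels[[length(seg_labels) + 1L]] <-
        c(rep("VIA", n_pre), rep("Fall", ev$n), rep("VIA", n_post))
    }
  }
  har_stream(do.call(rbind, seg_samples), rate_hz = rate_hz,
             labels = unlist(seg_labels))
}

#' Generate a synthetic cohort
#'
#' Draws one [subject_profile()] per subject with inter-subject spread
#' scaled by `subject_shift` — at the default 0.3 the class amplitude
#' multipliers span roughly ±30%, gait frequencies ±0.2 Hz, baseline
#' orientation ±9 degrees and noise ±20%, enough cross-subject feature
#' shift for personalization to matter; at 0 every subject is identical.
#' A single master seed fixes the profile draw and every per-subject
#' stream seed.
#'
#' @param n_subjects number of subjects (>= 2; default 10).
#' @param script per-subject [session_script()] (shared).
#' @param master_seed integer master seed.
#' @param subject_shift spread of the per-subject distribution shift
#'   (default 0.3).
#' @param rate_hz sampling frequency (default 50).
#' @return list of per-subject lists, each with `profile` and `stream`.
#' @export
make_cohort <- function(n_subjects = 10, script = default_session_script(),
                        master_seed = 1, subject_shift = 0.3,
                        rate_hz = 50) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  set.seed(master_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  profiles <- lapply(seq_len(n_subjects), function(i) {
    amp <- 1 + stats::runif(3L, -1, 1) * subject_shift
    names(amp) <- ACTIVITY_CLASSES
    subject_profile(
      id = i,
      amp_mult = amp,
      gyro_mult = 1 + stats::runif(1L, -1, 1) * subject_shift,
      orient_deg = stats::runif(1L, -30, 30) * subject_shift,
      freq_offset_hz = c(MIA = stats::runif(1L, -0.6, 0.6) * subject_shift,
                         VIA = stats::runif(1L, -0.6, 0.6) * subject_shift),
      noise_mult = 1 + stats::runif(1L, -0.67, 0.67) * subject_shift,
      seed = sub_seeds[i])
  })
  lapply(profiles, function(prof)
    list(profile = prof, stream = simulate_subject(prof, script, rate_hz)))
}
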