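#' Tracker configuration
#'
#' Parameters of one simulated eyetracker. Defaults mirror the consumer
#' device the coordinator was designed around: 60 Hz sampling and 0.5°
#' accuracy. `px_per_deg` converts angular accuracy into pixel noise; the
#' default 38 px/° assumes a 24-inch 1920x1080 display viewed from about
#' 60 cm.
#'
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param accuracy_deg Gaze accuracy in degrees of visual angle (>= 0); the
#'   simulator draws isotropic Gaussian noise with sd
#'   `accuracy_deg * px_per_deg` pixels per axis.
#' @param px_per_deg Pixels per degree of visual angle (> 0).
#' @param dropout_prob Probability that any sample is flagged invalid
#'   (tracking loss), in `[0, 1]`.
#' @param gap_mode What to emit between scripted fixations: `"invalid"`
#'   samples (default, conservative for fixation detection) or
#'   `"interpolate"` a straight saccade path.
#' @param pupil_base,pupil_sd Simulated pupil signal: constant baseline plus
#'   Gaussian noise (arbitrary units).
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(rate_hz = 60, accuracy_deg = 0.5, px_per_deg = 38,
                           dropout_prob = 0, gap_mode = c("invalid", "interpolate"),
                           pupil_base = 4, pupil_sd = 0.05) {
  stop_if_not_scalar_number(rate_hz, "rate_hz", min = 1e-9)
  stop_if_not_scalar_number(accuracy_deg, "accuracy_deg", min = 0)
  stop_if_not_scalar_number(px_per_deg, "px_per_deg", min = 1e-9)
  stop_if_not_scalar_number(dropout_prob, "dropout_prob", min = 0, max = 1)
  structure(list(rate_hz = rate_hz, accuracy_deg = accuracy_deg,
                 px_per_deg = px_per_deg, dropout_prob = dropout_prob,
                 gap_mode = match.arg(gap_mode),
                 pupil_base = pupil_base, pupil_sd = pupil_sd),
            class = "tracker_config")
}

#' Build a gaze script of intended fixations
#'
#' A script is the ground truth a simulated tracker realizes: a time-ordered,
#' non-overlapping sequence of intended fixations, each with a screen target
#' and an optional intended AOI label.
#'
#' @param target_x_px,target_y_px Fixation target coordinates (pixels).
#' @param onset_ms,offset_ms Fixation start/end times (ms, `offset > onset`).
#' @param label Optional intended AOI label (NA when none).
#' @return A `gaze_script` data frame.
#' @export
gaze_script <- function(target_x_px, target_y_px, onset_ms, offset_ms,
                        label = NA_character_) {
  df <- data.frame(target_x_px = as.numeric(target_x_px),
                   target_y_px = as.numeric(target_y_px),
                   onset_ms = as.integer(onset_ms),
                   offset_ms = as.integer(offset_ms),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$offset_ms <= df$onset_ms))
      stop("each fixation needs offset_ms > onset_ms", call. = FALSE)
    if (is.unsorted(df$onset_ms, strictly = TRUE) && nrow(df) > 1L)
      stop("fixation specs must be time-ordered", call. = FALSE)
    if (nrow(df) > 1L && any(df$onset_ms[-1] < df$offset_ms[-nrow(df)]))
      stop("fixation specs must not overlap", call. = FALSE)
  }
  class(df) <- c("gaze_script", "data.frame")
  df
}

#' Simulate a gaze stream from a fixation script
#'
#' Emits samples at the tracker period (1000 / `rate_hz` ms). While a
#' scripted fixation is on, sample positions are the target plus isotropic
#' Gaussian accuracy noise; between fixations, samples are either flagged
#' invalid or linearly interpolated, per `cfg$gap_mode`. A `dropout_prob`
#' fraction of samples is flagged invalid at random. Deterministic given
#' `seed`.
#'
#' @param script A `gaze_script`.
#' @param cfg A [tracker_config()].
#' @param seed Integer seed.
#' @param participant_id Participant id stamped on every sample.
#' @param t0_ms Time of the first sample (defaults to the script onset).
#' @param end_ms Last time to sample, exclusive (defaults to script offset).
#' @return A gaze-sample data frame
#'   (`participant_id,t_ms,x_px,y_px,pupil,valid`).
#' @export
stream_gaze <- function(script, cfg = tracker_config(), seed = NULL,
                        participant_id = "p01", t0_ms = NULL, end_ms = NULL) {
  stopifnot(inherits(script, "gaze_script"))
  if (nrow(script) == 0L) return(empty_gaze())
  t0 <- as.integer(t0_ms %||% script$onset_ms[1])
  tend <- as.integer(end_ms %||% script$offset_ms[nrow(script)])
  period <- 1000 / cfg$rate_hz
  if (tend <= t0) return(empty_gaze())
  with_seed(seed, {
    t <- as.integer(floor(t0 + period * seq.int(0L, floor((tend - t0 - 1e-9) / period))))
    n <- length(t)
    # which scripted fixation (if any) covers each sample time
    idx <- rep(NA_integer_, n)
    for (k in seq_len(nrow(script))) {
      on <- t >= script$onset_ms[k] & t < script$offset_ms[k]
      idx[on] <- k
    }
    x <- y <- rep(NA_real_, n)
    valid <- !is.na(idx)
    sdpx <- cfg$accuracy_deg * cfg$px_per_deg
    if (any(valid)) {
      x[valid] <- script$target_x_px[idx[valid]] + rnorm(sum(valid), 0, sdpx)
      y[valid] <- script$target_y_px[idx[valid]] + rnorm(sum(valid), 0, sdpx)
    }
    if (cfg$gap_mode == "interpolate" && any(!valid)) {
      gap <- which(!valid)
      x[gap] <- stats::approx(script$onset_ms, script$target_x_px, xout = t[gap],
                              rule = 2)$y + rnorm(length(gap), 0, sdpx)
      y[gap] <- stats::approx(script$onset_ms, script$target_y_px, xout = t[gap],
                              rule = 2)$y + rnorm(length(gap), 0, sdpx)
      valid <- rep(TRUE, n)
    }
    if (cfg$dropout_prob > 0)
      valid <- valid & runif(n) >= cfg$dropout_prob
    data.frame(participant_id = participant_id, t_ms = t,
               x_px = x, y_px = y,
               pupil = cfg$pupil_base + rnorm(n, 0, cfg$pupil_sd),
               valid = valid, stringsAsFactors = FALSE)
  })
}

#' Simulate one calibration attempt
#'
#' The attained accuracy is drawn from a zero-truncated normal quality
#' model (default mean 0.4°, sd 0.15°); the attempt succeeds when the
#' attained accuracy is strictly below `threshold_deg`. Point-level gaze is
#' not modeled — only the attempt-level outcome, which is what the
#' calibration policy consumes.
#'
#' @param quality_mean,quality_sd Parameters of the truncated-normal
#'   accuracy model (degrees); `quality_sd = 0` gives a deterministic
#'   accuracy, useful for forcing outcomes.
#' @param threshold_deg Success threshold in degrees (> 0).
#' @param seed Integer seed.
#' @param attempt_index 1-based index of this attempt.
#' @param points_shown Number of calibration points presented.
#' @return A `calibration_attempt` list with `attempt_index`,
#'   `achieved_accuracy_deg`, `points_shown`, `success`.
#' @export
simulate_calibration <- function(quality_mean = 0.4, quality_sd = 0.15,
                                 threshold_deg = 0.5, seed = NULL,
                                 attempt_index = 1L, points_shown = 9L) {
  stop_if_not_scalar_number(threshold_deg, "threshold_deg", min = 1e-9)
  stop_if_not_scalar_number(quality_sd, "quality_sd", min = 0)
  if (!is.numeric(quality_mean) || length(quality_mean) != 1L)
    stop("`quality_mean` must be a single number", call. = FALSE)
  acc <- with_seed(seed, rtnorm0(1, quality_mean, quality_sd))
  acc <- max(0, acc)
  structure(list(attempt_index = as.integer(attempt_index),
                 achieved_accuracy_deg = acc,
                 points_shown = as.integer(points_shown),
                 success = acc < threshold_deg),
            class = "calibration_attempt")
}
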