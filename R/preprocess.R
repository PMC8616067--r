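#' Linear-envelope preprocessing
#'
#' Raw sEMG is converted to standardized linear envelopes by zero-phase
#' high-pass filtering at 10 Hz, full-wave rectification, zero-phase low-pass
#' filtering at 10 Hz, and division by the session-wide median rectified
#' amplitude pooled over all muscles and trials.
#'
#' @name preprocessing
NULL

# Zero-phase Butterworth filtering with odd-reflection padding so edge
# transients stay negligible even on short series.
zero_phase_butter <- function(x, fs_hz, cutoff_hz, type, order = 4) {
  n <- length(x)
  min_len <- 3 * (order + 1)
  if (n < min_len) {
    stop(sprintf("series too short for filtering (need >= %d samples)", min_len))
  }
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = type)
  # the slowest Butterworth pole decays with tau ~ fs/(2*pi*fc*0.38); eight
  # cutoff periods leave transients below 1e-6 of the input magnitude
  pad <- min(n - 1L, max(min_len, ceiling(8 * fs_hz / cutoff_hz)))
  head_ref <- 2 * x[1] - x[(pad + 1L):2L]
  tail_ref <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(head_ref, x, tail_ref))
  y[(pad + 1L):(pad + n)]
}

#' High-pass filter a raw sEMG series
#'
#' 4th-order zero-phase Butterworth high-pass (forward-backward), removing
#' movement artifact and DC below `cutoff_hz`.
#'
#' @param x numeric series.
#' @param fs_hz sampling rate; must exceed `2 * cutoff_hz`.
#' @param cutoff_hz cutoff frequency, default 10 Hz.
#' @param order filter order (per pass), default 4.
#' @return filtered series, same length.
#' @export
emg_highpass <- function(x, fs_hz, cutoff_hz = 10, order = 4) {
  if (fs_hz <= 2 * cutoff_hz) stop("fs_hz must exceed 2 * cutoff_hz")
  if (!all(is.finite(x))) stop("input series must be finite")
  zero_phase_butter(x, fs_hz, cutoff_hz, "high", order)
}

#' Full-wave rectification
#'
#' @param x numeric series (finite).
#' @return elementwise absolute value.
#' @export
emg_rectify <- function(x) {
  if (!all(is.finite(x))) stop("input series must be finite")
  abs(x)
}

#' Low-pass envelope extraction
#'
#' 4th-order zero-phase Butterworth low-pass of a rectified series; negative
#' filter overshoot is clipped to zero so envelopes stay nonnegative.
#'
#' @inheritParams emg_highpass
#' @return smoothed nonnegative envelope, same length.
#' @export
emg_lowpass_envelope <- function(x, fs_hz, cutoff_hz = 10, order = 4) {
  if (fs_hz <= 2 * cutoff_hz) stop("fs_hz must exceed 2 * cutoff_hz")
  if (!all(is.finite(x))) stop("input series must be finite")
  pmax(zero_phase_butter(x, fs_hz, cutoff_hz, "low", order), 0)
}

#' Construct an envelope matrix
#'
#' @param values nonnegative muscle x time matrix (dimensionless after
#'   standardization).
#' @param fs_hz sampling rate.
#' @param muscle_labels one per row.
#' @param condition_label resistance level.
#' @param trial_id,participant_id identifiers.
#' @return object of class `envelope_matrix`.
#' @export
envelope_matrix <- function(values, fs_hz, muscle_labels = rownames(values),
                            condition_label = NA_integer_, trial_id = 1L,
                            participant_id = "P01") {
  if (!is.matrix(values) || !all(is.finite(values)) || any(values < 0)) {
    stop("values must be a finite nonnegative matrix")
  }
  rownames(values) <- muscle_labels
  structure(list(values = values, fs_hz = fs_hz,
                 muscle_labels = muscle_labels,
                 condition_label = condition_label, trial_id = trial_id,
                 participant_id = participant_id),
            class = "envelope_matrix")
}

#' @export
print.envelope_matrix <- function(x, ...) {
  cat(sprintf("<envelope_matrix> %d muscles x %d samples @ %g Hz | level %s\n",
              nrow(x$values), ncol(x$values), x$fs_hz, x$condition_label))
  invisible(x)
}

# Per-trial filter stages: rectified (pre-smoothing) signal and raw envelope.
envelope_stages <- function(session, highpass_hz = 10, lowpass_hz = 10,
                            order = 4) {
  rect <- t(apply(session$samples, 1, function(x) {
    emg_rectify(emg_highpass(x, session$fs_hz, highpass_hz, order))
  }))
  env <- t(apply(rect, 1, function(x) {
    emg_lowpass_envelope(x, session$fs_hz, lowpass_hz, order)
  }))
  list(rect = rect, env = env)
}

#' Standardize a session's envelopes by the pooled rectified median
#'
#' Divides every envelope value by a single session-wide scalar: the median
#' of the rectified (pre-smoothing) amplitude pooled over all muscles and
#' trials. Inter-muscle ratios are unchanged.
#'
#' @param envelopes list of [envelope_matrix()] objects (one per trial).
#' @param median_amplitude the pooled rectified median; if `NULL`, the
#'   median of the pooled envelope values themselves is used (only sensible
#'   when the rectified stage is unavailable).
#' @return list of standardized [envelope_matrix()] objects.
#' @export
standardize_session <- function(envelopes, median_amplitude = NULL) {
  if (length(envelopes) == 0) stop("empty session")
  if (is.null(median_amplitude)) {
    median_amplitude <- median(unlist(lapply(envelopes, function(e) e$values)))
  }
  if (!is.finite(median_amplitude) || median_amplitude <= 0) {
    stop_degenerate("session median amplitude is zero: degenerate session")
  }
  lapply(envelopes, function(e) {
    e$values <- e$values / median_amplitude
    e
  })
}

#' Preprocess a set of trials as one session
#'
#' Applies high-pass (10 Hz), rectification and low-pass (10 Hz) per muscle
#' and trial, then standardizes all trials by the single session-wide median
#' rectified amplitude.
#'
#' @param sessions list of [emg_session()] trials belonging to one
#'   recording session.
#' @param highpass_hz,lowpass_hz filter cutoffs (Hz).
#' @param order Butterworth order per pass.
#' @return list of standardized [envelope_matrix()] objects.
#' @export
preprocess_session <- function(sessions, highpass_hz = 10, lowpass_hz = 10,
                               order = 4) {
  if (length(sessions) == 0) stop("empty session")
  stages <- lapply(sessions, envelope_stages, highpass_hz = highpass_hz,
                   lowpass_hz = lowpass_hz, order = order)
  med <- median(unlist(lapply(stages, function(s) s$rect)))
  envs <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    envelope_matrix(stages[[i]]$env, s$fs_hz, s$muscle_labels,
                    s$condition_label, s$trial_id, s$participant_id)
  })
  standardize_session(envs, med)
}

#' Preprocess a single trial
#'
#' Convenience wrapper around [preprocess_session()] for a one-trial
#' session: the standardizing median is the trial's own pooled rectified
#' median.
#'
#' @param session an [emg_session()].
#' @inheritParams preprocess_session
#' @return an [envelope_matrix()].
#' @export
preprocess <- function(session, highpass_hz = 10, lowpass_hz = 10, order = 4) {
  preprocess_session(list(session), highpass_hz, lowpass_hz, order)[[1]]
}
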