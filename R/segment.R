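#' Kinematics-free motion-cycle segmentation
#'
#' Cycles are delimited by local minima of a composite envelope (the
#' per-sample sum over muscles), exploiting the periodicity of the motion so
#' that no crank-angle or IMU signal is needed.
#'
#' @name cycle_segmentation
NULL

#' Composite envelope across muscles
#'
#' @param env an [envelope_matrix()].
#' @return numeric series: per-sample sum over muscles.
#' @export
composite_envelope <- function(env) {
  colSums(env$values)
}

#' Infer the dominant cycle period from the autocorrelation
#'
#' Takes the smallest-lag local maximum of the autocorrelation function
#' whose height is within 50% of the strongest peak (the acf also peaks at
#' period multiples); used to set the default minimum separation between
#' cycle boundaries.
#'
#' @param series composite envelope.
#' @param fs_hz sampling rate.
#' @param min_lag_s shortest admissible period (s).
#' @param max_lag_s longest admissible period (s).
#' @return period estimate in seconds.
#' @export
infer_cadence <- function(series, fs_hz, min_lag_s = 0.25, max_lag_s = 3) {
  max_lag <- min(length(series) - 1L, round(max_lag_s * fs_hz))
  ac <- acf(series, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  lo <- max(2L, round(min_lag_s * fs_hz))
  if (lo + 1L >= length(ac)) stop_degenerate("series too short to infer cadence")
  idx <- (lo + 1L):(length(ac) - 1L)
  is_peak <- ac[idx] >= ac[idx - 1L] & ac[idx] >= ac[idx + 1L]
  peaks <- idx[is_peak]
  if (length(peaks) == 0) stop_degenerate("no periodicity found in composite")
  # prefer the fundamental: the acf also peaks at period multiples, so take
  # the smallest lag whose peak is comparable to the strongest one
  strong <- peaks[ac[peaks] >= 0.5 * max(ac[peaks])]
  (min(strong) - 1L) / fs_hz
}

# Prominence of a local minimum: elevation to the lower of the two maxima
# separating it from the nearest deeper point (or series edge) on each side.
minimum_prominence <- function(series, i) {
  v <- series[i]
  left <- if (i > 1L) {
    seg <- series[1:(i - 1L)]
    deeper <- which(seg < v)
    max(seg[if (length(deeper)) (max(deeper)):(i - 1L) else 1:(i - 1L)])
  } else v
  right <- if (i < length(series)) {
    seg <- series[(i + 1L):length(series)]
    deeper <- which(seg < v)
    ub <- if (length(deeper)) min(deeper) else length(seg)
    max(seg[1:ub])
  } else v
  min(left, right) - v
}

#' Detect cycle boundaries from envelope local minima
#'
#' Finds local minima separated by at least `min_period_s` and with
#' prominence at least `prominence_frac` of the series range; conflicts are
#' resolved in favor of the deeper minimum, then the earlier index. The
#' first/last sample is admitted as a boundary when the series rises away
#' from (falls into) that edge over half the minimum period, so that trials
#' starting or ending at a cycle boundary are bracketed completely.
#'
#' @param series nonnegative composite envelope.
#' @param fs_hz sampling rate.
#' @param min_period_s minimum boundary separation (s); default half the
#'   cadence inferred by [infer_cadence()].
#' @param prominence_frac prominence threshold as a fraction of
#'   `max(series) - min(series)`, default 0.2: high enough to reject the
#'   shallow dips between successive activation bursts within a cycle,
#'   which reach ~0.15-0.17 of the range on burst-like envelopes, while
#'   boundary valleys sit well above 0.4.
#' @return object of class `cycle_boundaries`: `start_indices` (1-based,
#'   strictly increasing) and `fs_hz`.
#' @export
detect_boundaries <- function(series, fs_hz, min_period_s = NULL,
                              prominence_frac = 0.2) {
  if (any(series < 0)) stop("series must be nonnegative")
  n <- length(series)
  rng <- max(series) - min(series)
  if (rng <= 0) stop_degenerate("constant series cannot be segmented")
  if (is.null(min_period_s)) {
    min_period_s <- 0.5 * infer_cadence(series, fs_hz)
  }
  if (min_period_s <= 0) stop("min_period_s must be positive")
  min_dist <- max(1L, round(min_period_s * fs_hz))

  d <- diff(series)
  # interior strict minima (first index of any flat valley)
  cand <- which(d[-1] > 0 & d[-length(d)] < 0) + 1L
  if (length(cand)) {
    prom <- vapply(cand, function(i) minimum_prominence(series, i), numeric(1))
    cand <- cand[prom >= prominence_frac * rng]
  }
  cand_val <- series[cand]

  # edge candidates: monotone-edge windows of half the minimum separation
  w <- max(2L, min_dist %/% 2L)
  if (n > w && series[1] <= min(series[1:w])) {
    cand <- c(cand, 1L); cand_val <- c(cand_val, series[1])
  }
  if (n > w && series[n] <= min(series[(n - w + 1L):n])) {
    cand <- c(cand, n); cand_val <- c(cand_val, series[n])
  }
  if (length(cand) < 2L) {
    stop_degenerate("fewer than 2 boundaries found: unsegmentable trial")
  }

  ord <- order(cand_val, cand)
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - accepted) >= min_dist)) {
      accepted <- c(accepted, cand[i])
    }
  }
  accepted <- sort(accepted)
  if (length(accepted) < 2L) {
    stop_degenerate("fewer than 2 boundaries found: unsegmentable trial")
  }
  structure(list(start_indices = accepted, fs_hz = fs_hz),
            class = "cycle_boundaries")
}

#' Split an envelope into motion cycles
#'
#' Cycles are the half-open blocks `[b_k, b_{k+1})` between consecutive
#' boundaries; samples before the first and after the last boundary
#' (partial cycles) are discarded. Concatenating the cycles reproduces the
#' spanned region exactly.
#'
#' @param env an [envelope_matrix()].
#' @param boundaries a `cycle_boundaries` object (or integer vector of
#'   1-based start indices).
#' @param min_len minimum admissible native cycle length (samples).
#' @return object of class `cycle_set`: list `cycles` of muscle x time
#'   blocks, plus `fs_hz` and `muscle_labels`.
#' @export
segment_cycles <- function(env, boundaries, min_len = 4L) {
  b <- if (inherits(boundaries, "cycle_boundaries")) {
    boundaries$start_indices
  } else {
    as.integer(boundaries)
  }
  if (length(b) < 2L || any(diff(b) <= 0)) {
    stop("need >= 2 strictly increasing boundaries")
  }
  if (min(b) < 1L || max(b) > ncol(env$values) + 1L) {
    stop("boundary outside signal")
  }
  cycles <- lapply(seq_len(length(b) - 1L), function(k) {
    env$values[, b[k]:(b[k + 1L] - 1L), drop = FALSE]
  })
  if (any(vapply(cycles, ncol, integer(1)) < min_len)) {
    stop_degenerate("cycle shorter than the configured minimum")
  }
  structure(list(cycles = cycles, fs_hz = env$fs_hz,
                 muscle_labels = env$muscle_labels,
                 condition_label = env$condition_label,
                 trial_id = env$trial_id,
                 participant_id = env$participant_id),
            class = "cycle_set")
}

#' Export cycle boundaries as a two-column CSV
#'
#' @param boundaries a `cycle_boundaries` object.
#' @param path output path; columns `cycle_index`, `start_sample`.
#' @return `path`, invisibly.
#' @export
write_boundaries_csv <- function(boundaries, path) {
  data.table::fwrite(data.frame(
    cycle_index = seq_along(boundaries$start_indices),
    start_sample = boundaries$start_indices
  ), path)
  invisible(path)
}

#' @export
print.cycle_set <- function(x, ...) {
  lens <- vapply(x$cycles, ncol, integer(1))
  cat(sprintf("<cycle_set> %d cycles x %d muscles, native lengths %d-%d samples\n",
              length(x$cycles), length(x$muscle_labels), min(lens), max(lens)))
  invisible(x)
}
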