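#' Default planted muscle weighting matrix
#'
#' Muscle-by-phase weights used by [synth_config()]. Rows are the four large
#' cycling muscles (vastus lateralis VLAT, biceps femoris BF, tibialis
#' anterior TA, gastrocnemius medialis GAM); columns are the three pedaling
#' phases (traction, power initiation, power end). The pattern encodes the
#' canonical activation order in cycling: TA during traction, VLAT at power
#' onset, BF/GAM coactivation closing the power phase.
#'
#' @format numeric matrix, 4 muscles x 3 phases, dimensionless weights.
#' @export
default_planted_W <- function() {
  W <- rbind(
    VLAT = c(0.10, 1.00, 0.20),
    BF   = c(0.10, 0.10, 0.45),
    TA   = c(1.00, 0.10, 0.10),
    GAM  = c(0.10, 0.20, 0.90)
  )
  colnames(W) <- c("traction", "power_init", "power_end")
  W
}

#' Resistance-level schedules for the synthetic generator
#'
#' Package constants mapping stationary-bike resistance levels 2-5 onto
#' generator parameters: the VLAT weight in the power-initiation phase grows
#' with level, BF gradually overtakes GAM in the power-end phase, TA drops
#' only at the highest level, and both inter-cycle jitters shrink as force
#' demand rises (higher force recruits more stable cycles). Magnitudes are
#' package defaults; only the directions are empirically motivated.
#'
#' @return named list of per-level vectors (names `"2"`..`"5"`).
#' @export
resistance_schedule <- function() {
  lv <- as.character(2:5)
  sched <- list(
    vlat_power_gain     = c(1.00, 1.15, 1.30, 1.45),
    bf_power_end        = c(0.45, 0.60, 0.75, 0.90),
    gam_power_end       = c(0.90, 0.85, 0.80, 0.75),
    ta_traction         = c(1.00, 1.00, 1.00, 0.85),
    timing_jitter_sd    = c(0.035, 0.030, 0.025, 0.020),
    amplitude_jitter_sd = c(0.20, 0.15, 0.10, 0.05)
  )
  lapply(sched, function(v) stats::setNames(v, lv))
}

#' Synthetic sEMG generator configuration
#'
#' Defaults emulate the study conditions: 4 muscles, 3 planted phases,
#' 1500 Hz sampling, ~1 s cadence, 12 cycles per trial, mild timing and
#' amplitude jitter, a 20-450 Hz interference-pattern carrier and 30 dB
#' envelope-to-noise ratio.
#'
#' @param n_muscles number of channels.
#' @param n_phases number of planted synergies.
#' @param planted_W nonnegative muscle x phase weight matrix.
#' @param phase_centers bump centers, fraction of cycle in `[0, 1)`,
#'   strictly increasing. The defaults concentrate activity inside the
#'   cycle so the boundary sits in a quiet valley, as in real pedaling
#'   envelopes; minima-based segmentation requires the boundary valley to
#'   be the deepest per-cycle minimum.
#' @param phase_widths Gaussian bump standard deviations, fraction of cycle.
#' @param cadence_s nominal cycle period in seconds.
#' @param n_cycles cycles per trial.
#' @param timing_jitter_sd per-cycle, per-phase jitter of bump center (and
#'   multiplicative log-sd of bump width), fraction of cycle.
#' @param amplitude_jitter_sd lognormal sigma of the per (cycle, phase,
#'   muscle) amplitude factor.
#' @param carrier_band_hz two-element band (Hz) of the raw sEMG carrier.
#' @param snr_db envelope-to-additive-noise power ratio in dB.
#' @param fs_hz sampling rate (Hz).
#' @param uv_scale microvolt scale of the planted envelope.
#' @param seed integer root seed; each trial derives its own stream from
#'   `(seed, trial_id)`.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_muscles = 4L,
                         n_phases = 3L,
                         planted_W = default_planted_W(),
                         phase_centers = c(0.25, 0.50, 0.75),
                         phase_widths = c(0.10, 0.10, 0.10),
                         cadence_s = 1.0,
                         n_cycles = 12L,
                         timing_jitter_sd = 0.02,
                         amplitude_jitter_sd = 0.05,
                         carrier_band_hz = c(20, 450),
                         snr_db = 30,
                         fs_hz = 1500,
                         uv_scale = 80,
                         seed = 1L) {
  cfg <- structure(list(
    n_muscles = as.integer(n_muscles), n_phases = as.integer(n_phases),
    planted_W = planted_W, phase_centers = phase_centers,
    phase_widths = phase_widths, cadence_s = cadence_s,
    n_cycles = as.integer(n_cycles), timing_jitter_sd = timing_jitter_sd,
    amplitude_jitter_sd = amplitude_jitter_sd,
    carrier_band_hz = carrier_band_hz, snr_db = snr_db, fs_hz = fs_hz,
    uv_scale = uv_scale, seed = as.integer(seed),
    condition_label = NA_integer_
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  W <- cfg$planted_W
  if (!is.matrix(W) || !all(is.finite(W))) {
    stop("planted_W must be a finite numeric matrix")
  }
  if (any(W < 0)) stop("planted_W must be nonnegative")
  if (nrow(W) != cfg$n_muscles || ncol(W) != cfg$n_phases) {
    stop("planted_W must be n_muscles x n_phases")
  }
  pc <- cfg$phase_centers
  if (length(pc) != cfg$n_phases || any(pc < 0) || any(pc >= 1) ||
      any(diff(pc) <= 0)) {
    stop("phase_centers must be strictly increasing within [0, 1)")
  }
  pw <- cfg$phase_widths
  if (length(pw) != cfg$n_phases || any(pw <= 0) || any(pw >= 1)) {
    stop("phase_widths must lie in (0, 1)")
  }
  if (cfg$fs_hz <= 2 * max(cfg$carrier_band_hz)) {
    stop("fs_hz must exceed twice the carrier band upper edge")
  }
  if (cfg$n_cycles < 1L) stop("n_cycles must be >= 1")
  if (cfg$cadence_s <= 0) stop("cadence_s must be positive")
  if (!is.finite(cfg$snr_db)) stop("snr_db must be finite")
  invisible(cfg)
}

#' Apply a resistance-level effect to a generator configuration
#'
#' Rewrites the planted weights and jitter magnitudes of `config` according
#' to the monotone per-level schedules of [resistance_schedule()]. Assumes
#' the default muscle/phase ordering (VLAT, BF, TA, GAM x traction,
#' power_init, power_end).
#'
#' @param config a [synth_config()].
#' @param level integer resistance level in 2..5 (level 1, freewheeling
#'   warmup, is not modeled).
#' @return modified `synth_config` with `condition_label = level`.
#' @export
apply_resistance_effect <- function(config, level) {
  if (length(level) != 1L || !level %in% 2:5) {
    stop("level must be a single integer in 2..5")
  }
  s <- resistance_schedule()
  key <- as.character(level)
  W <- config$planted_W
  base <- default_planted_W()
  W["VLAT", "power_init"] <- base["VLAT", "power_init"] * s$vlat_power_gain[key]
  W["BF", "power_end"] <- s$bf_power_end[key]
  W["GAM", "power_end"] <- s$gam_power_end[key]
  W["TA", "traction"] <- s$ta_traction[key]
  config$planted_W <- W
  config$timing_jitter_sd <- unname(s$timing_jitter_sd[key])
  config$amplitude_jitter_sd <- unname(s$amplitude_jitter_sd[key])
  config$condition_label <- as.integer(level)
  validate_synth_config(config)
  config
}

#' Construct an sEMG recording session object
#'
#' @param samples muscle x time numeric matrix, microvolts.
#' @param fs_hz sampling rate.
#' @param muscle_labels channel names, one per row.
#' @param condition_label resistance level (or `NA`).
#' @param trial_id,participant_id identifiers.
#' @return object of class `emg_session`.
#' @export
emg_session <- function(samples, fs_hz, muscle_labels = rownames(samples),
                        condition_label = NA_integer_, trial_id = 1L,
                        participant_id = "P01") {
  if (!is.matrix(samples) || !all(is.finite(samples))) {
    stop("samples must be a finite numeric matrix (muscle x time)")
  }
  if (is.null(muscle_labels)) {
    muscle_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(muscle_labels) != nrow(samples)) {
    stop("one muscle label per row is required")
  }
  if (fs_hz <= 0) stop("fs_hz must be positive")
  rownames(samples) <- muscle_labels
  structure(list(samples = samples, fs_hz = fs_hz,
                 muscle_labels = muscle_labels,
                 condition_label = condition_label, trial_id = trial_id,
                 participant_id = participant_id),
            class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("<emg_session> %s trial %s | %d muscles x %d samples @ %g Hz | level %s\n",
              x$participant_id, x$trial_id, nrow(x$samples), ncol(x$samples),
              x$fs_hz, x$condition_label))
  invisible(x)
}

# Planted envelope (muscle x time, microvolts) for one trial given the
# jittered per-cycle bump parameters. Bumps are Gaussian in cycle time,
# truncated at +/- 4 sd.
build_planted_envelope <- function(cfg, centers_frac, widths_frac, amp) {
  L <- round(cfg$cadence_s * cfg$fs_hz)
  n <- L * cfg$n_cycles
  E <- matrix(0, cfg$n_muscles, n)
  for (c_i in seq_len(cfg$n_cycles)) {
    off <- (c_i - 1L) * L
    for (p in seq_len(cfg$n_phases)) {
      ctr <- off + centers_frac[c_i, p] * L
      sd_s <- widths_frac[c_i, p] * L
      lo <- max(1L, floor(ctr - 4 * sd_s))
      hi <- min(n, ceiling(ctr + 4 * sd_s))
      if (lo > hi) next
      t_idx <- lo:hi
      bump <- exp(-0.5 * ((t_idx - ctr) / sd_s)^2)
      for (m in seq_len(cfg$n_muscles)) {
        E[m, t_idx] <- E[m, t_idx] +
          cfg$planted_W[m, p] * amp[c_i, p, m] * bump
      }
    }
  }
  E * cfg$uv_scale
}

# Band-limited unit-mean-absolute-value carrier noise, one channel.
carrier_noise <- function(n, fs_hz, band) {
  x <- rnorm(n)
  bf <- signal::butter(4, band / (fs_hz / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / mean(abs(y))
}

#' Generate one synthetic sEMG trial with ground truth
#'
#' Builds, per cycle and phase, a truncated-Gaussian activation bump whose
#' center and width are jittered by `timing_jitter_sd` and whose amplitude is
#' scaled by `planted_W` times a lognormal per-(cycle, phase, muscle) jitter
#' factor. The summed envelope amplitude-modulates band-limited zero-mean
#' carrier noise (normalized to unit mean absolute value, so the rectified
#' smoothed signal recovers the planted envelope), and white sensor noise set
#' by `snr_db` is added. Deterministic given `(config$seed, trial_id)`.
#'
#' @param config a [synth_config()].
#' @param trial_id integer; selects the trial's random stream.
#' @param participant_id passed through to the session.
#' @return list with elements `session` ([emg_session()]) and `truth`
#'   (class `ground_truth`: `true_boundaries` (1-based cycle start samples),
#'   `true_W`, `true_H_per_cycle` (cycle x phase x 200 normalized-time
#'   activations), per-cycle jittered centers/widths, amplitude factors,
#'   the planted envelope, and `condition_label`).
#' @export
generate_trial <- function(config, trial_id = 1L, participant_id = "P01") {
  validate_synth_config(config)
  if (config$snr_db < -10) {
    warning("snr_db below -10 dB: output is essentially all noise")
  }
  cfg <- config
  L <- round(cfg$cadence_s * cfg$fs_hz)
  n <- L * cfg$n_cycles
  t_norm <- 200L

  out <- with_local_seed(derive_seed(cfg$seed, trial_id), function() {
    centers <- matrix(rep(cfg$phase_centers, each = cfg$n_cycles),
                      cfg$n_cycles, cfg$n_phases)
    centers <- centers + matrix(rnorm(length(centers), 0, cfg$timing_jitter_sd),
                                cfg$n_cycles, cfg$n_phases)
    widths <- matrix(rep(cfg$phase_widths, each = cfg$n_cycles),
                     cfg$n_cycles, cfg$n_phases)
    widths <- widths * exp(matrix(rnorm(length(widths), 0, cfg$timing_jitter_sd),
                                  cfg$n_cycles, cfg$n_phases))
    amp <- array(exp(rnorm(cfg$n_cycles * cfg$n_phases * cfg$n_muscles,
                           0, cfg$amplitude_jitter_sd)),
                 dim = c(cfg$n_cycles, cfg$n_phases, cfg$n_muscles))

    E <- build_planted_envelope(cfg, centers, widths, amp)
    sig <- matrix(0, cfg$n_muscles, n)
    for (m in seq_len(cfg$n_muscles)) {
      sig[m, ] <- E[m, ] * carrier_noise(n, cfg$fs_hz, cfg$carrier_band_hz)
    }
    p_sig <- mean(sig^2)
    sd_noise <- sqrt(p_sig * 10^(-cfg$snr_db / 10))
    sig <- sig + matrix(rnorm(length(sig), 0, sd_noise), nrow(sig))
    list(sig = sig, E = E, centers = centers, widths = widths, amp = amp)
  })

  grid <- (seq_len(t_norm) - 1) / (t_norm - 1)
  H_true <- array(0, dim = c(cfg$n_cycles, cfg$n_phases, t_norm))
  for (c_i in seq_len(cfg$n_cycles)) {
    for (p in seq_len(cfg$n_phases)) {
      H_true[c_i, p, ] <- exp(-0.5 * ((grid - out$centers[c_i, p]) /
                                        out$widths[c_i, p])^2)
    }
  }

  muscles <- rownames(cfg$planted_W)
  if (is.null(muscles)) muscles <- paste0("ch", seq_len(cfg$n_muscles))
  session <- emg_session(out$sig, cfg$fs_hz, muscles,
                         condition_label = cfg$condition_label,
                         trial_id = trial_id,
                         participant_id = participant_id)
  truth <- structure(list(
    true_boundaries = as.integer((seq_len(cfg$n_cycles) - 1L) * L + 1L),
    cycle_len = L,
    true_W = cfg$planted_W,
    true_H_per_cycle = H_true,
    centers = out$centers, widths = out$widths, amplitude_factors = out$amp,
    planted_envelope = out$E,
    condition_label = cfg$condition_label
  ), class = "ground_truth")
  list(session = session, truth = truth)
}

# Mean planted temporal patterns (phase x t_norm) with no jitter, used as a
# reference model for recovery checks.
planted_reference_model <- function(config, t_norm = 200L) {
  grid <- (seq_len(t_norm) - 1) / (t_norm - 1)
  H <- t(vapply(seq_len(config$n_phases), function(p) {
    exp(-0.5 * ((grid - config$phase_centers[p]) / config$phase_widths[p])^2)
  }, numeric(t_norm)))
  synergy_model(W = config$planted_W, H = H, vaf = 1, converged = TRUE,
                n_iter = 0L)
}
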