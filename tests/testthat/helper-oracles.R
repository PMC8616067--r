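# Brute-force enumeration oracle for the two-sided Mann-Whitney U test:
# the null distribution of U over all C(nx+ny, nx) group assignments of the
# pooled ranks, with the two-sided p doubling the smaller tail (capped at 1).
mw_exact_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  assignments <- utils::combn(nx + ny, nx)
  u_null <- apply(assignments, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  p <- if (u_obs > nx * ny / 2) {
    2 * mean(u_null >= u_obs)
  } else {
    2 * mean(u_null <= u_obs)
  }
  list(U = u_obs, p = min(p, 1))
}

# Small, fast generator configuration for plumbing tests: short trial,
# narrow carrier so low sampling rates stay valid.
small_cfg <- function(...) {
  synth_config(n_cycles = 6L, fs_hz = 500, carrier_band_hz = c(20, 150),
               uv_scale = 50, ...)
}

# Planted per-muscle mean cycle (muscle x t_norm) implied by a config with
# no jitter: W %*% H with Gaussian bumps at the configured centers/widths.
planted_mean_cycle <- function(cfg, t_norm = 200L) {
  grid <- (seq_len(t_norm) - 1) / (t_norm - 1)
  H <- t(vapply(seq_len(cfg$n_phases), function(p) {
    exp(-0.5 * ((grid - cfg$phase_centers[p]) / cfg$phase_widths[p])^2)
  }, numeric(t_norm)))
  cfg$planted_W %*% H
}

# Phase x normalized-time reference activations implied by a config's
# centers/widths (no jitter).
planted_H_ref <- function(cfg, t_norm = 200L) {
  grid <- (seq_len(t_norm) - 1) / (t_norm - 1)
  t(vapply(seq_len(cfg$n_phases), function(p) {
    exp(-0.5 * ((grid - cfg$phase_centers[p]) / cfg$phase_widths[p])^2)
  }, numeric(t_norm)))
}

# Normalized cycle set straight from ground truth boundaries (bypasses
# boundary detection when a test wants to isolate downstream stages).
normalized_from_truth <- function(gen, env, t_norm = 200L) {
  b <- c(gen$truth$true_boundaries, ncol(env$values) + 1L)
  normalize_cycles(segment_cycles(env, b), t_norm)
}
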