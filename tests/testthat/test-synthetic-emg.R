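test_that("generation is deterministic given seed and varies across trials", {
  cfg <- small_cfg(seed = 42L)
  a <- generate_trial(cfg, trial_id = 1L)
  b <- generate_trial(cfg, trial_id = 1L)
  expect_identical(a$session$samples, b$session$samples)
  expect_identical(a$truth$centers, b$truth$centers)
  c2 <- generate_trial(cfg, trial_id = 2L)
  expect_false(identical(a$session$samples, c2$session$samples))
})

test_that("ground-truth boundaries follow the configured cadence", {
  cfg <- synth_config(n_cycles = 12L, cadence_s = 1, fs_hz = 1500)
  gen <- generate_trial(cfg, 1L)
  tb <- gen$truth$true_boundaries
  expect_length(tb, 12L)
  expect_true(all(diff(tb) == 1500L))
  expect_identical(tb[1], 1L)
  expect_equal(ncol(gen$session$samples), 12L * 1500L)
})

test_that("rectified+smoothed output reconstructs the planted envelope", {
  cfg <- synth_config(timing_jitter_sd = 0, amplitude_jitter_sd = 0,
                      snr_db = 60)
  gen <- generate_trial(cfg, 1L)
  env <- preprocess(gen$session)
  E <- gen$truth$planted_envelope
  # per-muscle shape correlation on the raw (single-pass) envelopes
  for (m in seq_len(4)) {
    expect_gt(cor(env$values[m, ], E[m, ]), 0.9)
  }
  # cycle-averaged comparison removes the carrier's irreducible rectified
  # fluctuation; standardization makes units arbitrary, so fit one scalar
  L <- gen$truth$cycle_len
  rec <- tru <- matrix(0, nrow(E), L)
  for (k in seq_len(cfg$n_cycles) - 1L) {
    idx <- (k * L + 1L):((k + 1L) * L)
    rec <- rec + env$values[, idx]
    tru <- tru + E[, idx]
  }
  s <- sum(rec * tru) / sum(rec^2)
  rel_rms <- sqrt(sum((rec * s - tru)^2) / sum(tru^2))
  expect_lt(rel_rms, 0.05)
})

test_that("generator rejects invalid configurations and warns on all-noise", {
  expect_error(synth_config(planted_W = matrix(-1, 4, 3)), "nonnegative")
  expect_error(synth_config(phase_centers = c(0.5, 0.3, 0.7)), "increasing")
  expect_error(synth_config(fs_hz = 100), "carrier")
  expect_error(synth_config(n_cycles = 0), "n_cycles")
  expect_warning(generate_trial(small_cfg(snr_db = -20), 1L), "noise")
})

test_that("resistance schedules are monotone in the documented directions", {
  base <- synth_config()
  cfgs <- lapply(2:5, function(l) apply_resistance_effect(base, l))
  tj <- vapply(cfgs, function(c) c$timing_jitter_sd, numeric(1))
  aj <- vapply(cfgs, function(c) c$amplitude_jitter_sd, numeric(1))
  expect_true(all(diff(tj) < 0))
  expect_true(all(diff(aj) < 0))
  bf <- vapply(cfgs, function(c) c$planted_W["BF", "power_end"], numeric(1))
  expect_true(all(diff(bf) > 0))
  vlat <- vapply(cfgs, function(c) sum(c$planted_W["VLAT", ]), numeric(1))
  expect_gte(vlat[4], vlat[1])
  # BF overtakes GAM at high force only
  expect_lt(cfgs[[1]]$planted_W["BF", "power_end"],
            cfgs[[1]]$planted_W["GAM", "power_end"])
  expect_gt(cfgs[[4]]$planted_W["BF", "power_end"],
            cfgs[[4]]$planted_W["GAM", "power_end"])
  expect_error(apply_resistance_effect(base, 1), "2..5")
  expect_error(apply_resistance_effect(base, 6), "2..5")
})

test_that("preprocessed envelope correlates with planted activation", {
  cfg <- synth_config(timing_jitter_sd = 0, snr_db = 20, seed = 3L)
  gen <- generate_trial(cfg, 1L)
  env <- preprocess(gen$session)
  E <- gen$truth$planted_envelope
  for (m in seq_len(4)) {
    expect_gt(cor(env$values[m, ], E[m, ]), 0.9)
  }
})
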