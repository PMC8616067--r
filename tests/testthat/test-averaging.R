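test_that("time normalization preserves identity, lines and integrals", {
  m <- matrix(abs(rnorm(400)), 2, 200)
  expect_equal(time_normalize(m, 200L), m, ignore_attr = TRUE)
  ramp <- matrix(seq(0, 1, length.out = 57), 1)
  out <- time_normalize(ramp, 200L)
  expect_lt(max(abs(out - seq(0, 1, length.out = 200))), 1e-9)
  # integral (mean x duration) of a smooth bump is preserved within 2%
  t_native <- seq(0, 1, length.out = 313)
  bump <- matrix(exp(-0.5 * ((t_native - 0.4) / 0.1)^2), 1)
  out_b <- time_normalize(bump, 200L)
  expect_lt(abs(mean(out_b) - mean(bump)) / mean(bump), 0.02)
  expect_error(time_normalize(matrix(1, 1, 3), 200L),
               class = "emgsynergy_degenerate")
})

test_that("anchors locate onset, peak and offset of activation shapes", {
  t_norm <- 200L
  grid <- (seq_len(t_norm) - 1) / (t_norm - 1)
  gauss <- matrix(exp(-0.5 * ((grid - 0.5) / 0.1)^2), 1)
  a <- detect_anchors(gauss)
  expect_lte(abs(a$peak - 100), 1)
  expect_true(a$onset < a$peak && a$peak < a$offset)
  # rectangular pulse on [0.3, 0.6]: onset/offset at the step edges
  rect <- matrix(as.numeric(grid >= 0.3 & grid <= 0.6), 1)
  ar <- detect_anchors(rect)
  expect_lte(abs(ar$onset - 0.3 * t_norm), 2)
  expect_lte(abs(ar$offset - 0.6 * t_norm), 2)
  # an all-zero muscle has null anchors
  two <- rbind(gauss, 0)
  a2 <- detect_anchors(two)
  expect_true(all(is.na(a2[2, c("onset", "peak", "offset")])))
})

test_that("averaging identical cycles is idempotent", {
  cyc <- matrix(abs(rnorm(300)), 3, 100)
  env <- envelope_matrix(cbind(cyc, cyc, cyc), 100, letters[1:3])
  cs <- segment_cycles(env, c(1L, 101L, 201L, 301L))
  ncs <- normalize_cycles(cs, 100L)
  avg <- average_cycles(ncs)
  expect_lt(max(abs(avg$matrix - cyc)), 1e-9)
  expect_identical(avg$n_cycles_used, 3L)
})

test_that("anchor alignment preserves peaks better than naive averaging", {
  t_norm <- 200L
  grid <- (seq_len(t_norm) - 1) / (t_norm - 1)
  shift <- 0.05
  c1 <- matrix(exp(-0.5 * ((grid - 0.5 + shift) / 0.08)^2), 1)
  c2 <- matrix(exp(-0.5 * ((grid - 0.5 - shift) / 0.08)^2), 1)
  env <- envelope_matrix(cbind(c1, c2), 200, "m")
  cs <- segment_cycles(env, c(1L, 201L, 401L))
  ncs <- normalize_cycles(cs, t_norm)
  aligned_peak <- max(average_cycles(ncs)$matrix)
  naive_peak <- max((c1 + c2) / 2)
  expect_gte(aligned_peak, naive_peak)
})

test_that("average of a clean planted trial matches the planted cycle", {
  cfg <- synth_config(timing_jitter_sd = 0, amplitude_jitter_sd = 0,
                      snr_db = 40, seed = 4L)
  gen <- generate_trial(cfg, 1L)
  env <- preprocess(gen$session)
  ncs <- normalized_from_truth(gen, env)
  avg <- average_cycles(ncs)
  planted <- planted_mean_cycle(cfg)
  for (m in seq_len(4)) {
    expect_gt(cor(avg$matrix[m, ], planted[m, ]), 0.98)
  }
})

test_that("averaging jittered cycles shrinks the residual to the truth", {
  cfg <- synth_config(timing_jitter_sd = 0.04, amplitude_jitter_sd = 0.1,
                      snr_db = 30, seed = 9L)
  gen <- generate_trial(cfg, 1L)
  env <- preprocess(gen$session)
  ncs <- normalized_from_truth(gen, env)
  avg <- average_cycles(ncs)
  planted <- planted_mean_cycle(cfg)
  # compare shapes scale-free: normalize every trace to unit RMS
  unit <- function(x) x / sqrt(mean(x^2))
  resid_avg <- mean(vapply(seq_len(4), function(m) {
    mean((unit(avg$matrix[m, ]) - unit(planted[m, ]))^2)
  }, numeric(1)))
  per_cycle <- vapply(seq_len(dim(ncs$tensor)[1]), function(k) {
    mean(vapply(seq_len(4), function(m) {
      mean((unit(ncs$tensor[k, m, ]) - unit(planted[m, ]))^2)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(resid_avg, min(per_cycle))
})

test_that("the anchor warp is monotone in time", {
  set.seed(11)
  for (rep in 1:20) {
    src <- sort(sample(5:195, 3))
    dst <- sort(sample(5:195, 3))
    pos <- stats::approx(c(1, dst, 200), c(1, src, 200),
                         xout = 1:200, rule = 2)$y
    expect_true(all(diff(pos) >= 0))
  }
})
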