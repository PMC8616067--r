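test_that("relative contribution follows its closed form", {
  # single phase gets everything
  expect_equal(relative_contribution(matrix(1, 4, 1), matrix(1, 1, 10)), 1,
               ignore_attr = TRUE)
  # column sums (2, 1) x row sums (3, 6) -> equal shares
  W <- rbind(c(2, 0.5), c(0, 0.5))
  H <- rbind(c(1, 1, 1), c(2, 2, 2))
  expect_equal(unname(relative_contribution(W, H)), c(0.5, 0.5))
  # joint rescaling leaves fractions unchanged
  expect_equal(relative_contribution(W * 7, H * 0.3),
               relative_contribution(W, H))
  # random instances vs the hand formula; always a simplex point
  set.seed(10)
  for (i in 1:10) {
    m <- sample(3:6, 1); n <- sample(2:4, 1); t_len <- sample(5:30, 1)
    Wr <- matrix(abs(rnorm(m * n)), m, n)
    Hr <- matrix(abs(rnorm(n * t_len)), n, t_len)
    expected <- colSums(Wr) * rowSums(Hr) / sum(colSums(Wr) * rowSums(Hr))
    got <- relative_contribution(Wr, Hr)
    expect_equal(got, expected, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
    # permutation equivariance
    p <- sample(n)
    expect_equal(unname(relative_contribution(Wr[, p], Hr[p, ])),
                 unname(expected[p]), tolerance = 1e-12)
  }
  expect_error(relative_contribution(matrix(0, 2, 2), matrix(0, 2, 3)),
               class = "emgsynergy_degenerate")
})

test_that("stability indices hit their correlation anchors", {
  same <- rbind(c(1, 2, 3, 2), c(1, 2, 3, 2), c(1, 2, 3, 2))
  expect_equal(temporal_stability(same), 1.0)
  anti <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(temporal_stability(anti), -1.0)
  expect_equal(spatial_stability(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1))), -1.0)
  expect_equal(spatial_stability(rbind(c(1, 2, 3), c(2, 4, 6))), 1.0)
  # constant rows are skipped; all-constant input is degenerate
  mixed <- rbind(c(1, 1, 1, 1), c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(temporal_stability(mixed), 1.0)
  expect_error(temporal_stability(rbind(c(1, 1), c(2, 2))),
               class = "emgsynergy_degenerate")
  expect_error(spatial_stability(rbind(c(1, 2), c(2, 1))), "muscles")
})

test_that("stability is invariant to a common positive rescaling", {
  set.seed(12)
  H_set <- matrix(abs(rnorm(5 * 50)), 5, 50)
  expect_equal(temporal_stability(H_set * 13), temporal_stability(H_set))
  W_set <- matrix(abs(rnorm(5 * 4)), 5, 4)
  expect_equal(spatial_stability(W_set * 0.01), spatial_stability(W_set))
})

test_that("per-cycle models recover planted weights on clean trials", {
  cfg <- synth_config(timing_jitter_sd = 0, amplitude_jitter_sd = 0,
                      snr_db = 40, seed = 8L)
  gen <- generate_trial(cfg, 1L)
  env <- preprocess(gen$session)
  ncs <- normalized_from_truth(gen, env)
  ref <- synergy_model(cfg$planted_W, planted_H_ref(cfg))
  pcm <- per_cycle_models(ncs, ref, seed = 1L)
  expect_identical(pcm$n_cycles, cfg$n_cycles)
  for (mod in pcm$models) {
    for (p in 1:3) {
      expect_gte(cor(mod$W[, p], cfg$planted_W[, p]), 0.98)
    }
  }
  st <- stability_indices(pcm)
  expect_true(all(st$temporal >= -1 & st$temporal <= 1))
  expect_true(all(st$spatial >= -1 & st$spatial <= 1))
  expect_true(all(st$temporal > 0.95))
})

test_that("failed cycles are dropped with bookkeeping", {
  cfg <- small_cfg(seed = 2L)
  gen <- generate_trial(cfg, 1L)
  env <- preprocess(gen$session)
  ncs <- normalized_from_truth(gen, env)
  ncs$tensor[3, , ] <- 0  # force one degenerate cycle
  ref <- synergy_model(cfg$planted_W, planted_H_ref(cfg))
  expect_warning(pcm <- per_cycle_models(ncs, ref, seed = 1L), "dropped")
  expect_identical(pcm$n_cycles, cfg$n_cycles - 1L)
  expect_false(3L %in% pcm$cycle_index)
})

test_that("fixed-W projection mode reproduces temporal patterns", {
  cfg <- synth_config(timing_jitter_sd = 0, amplitude_jitter_sd = 0,
                      snr_db = 40, seed = 13L)
  gen <- generate_trial(cfg, 1L)
  env <- preprocess(gen$session)
  ncs <- normalized_from_truth(gen, env)
  ref <- synergy_model(cfg$planted_W, planted_H_ref(cfg))
  H_ref <- ref$H
  pcm <- per_cycle_models(ncs, ref, mode = "project", seed = 1L)
  for (mod in pcm$models[1:3]) {
    for (p in 1:3) {
      expect_gt(cor(mod$H[p, ], H_ref[p, ]), 0.95)
    }
  }
})
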