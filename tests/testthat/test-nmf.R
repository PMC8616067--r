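test_that("exact low-rank structure is recovered with near-perfect VAF", {
  set.seed(1)
  w <- abs(rnorm(5)) + 0.1
  h <- abs(rnorm(40)) + 0.1
  M <- outer(w, h)
  fit <- nmf(M, 1L, seed = 1L, restarts = 3L)
  expect_gte(fit$vaf, 0.9999)
})

test_that("VAF matches its definition on constructed residuals", {
  set.seed(2)
  W <- matrix(abs(rnorm(8)), 4, 2)
  H <- matrix(abs(rnorm(60)), 2, 30)
  R <- W %*% H
  expect_equal(vaf(R, W, H), 1.0)
  expect_equal(vaf(R, W * 0, H * 0), 0.0)
  # residual E confined to extra columns, sized so ||E||^2/||M||^2 = 0.04
  Wz <- cbind(W, 0)
  Hz <- rbind(cbind(H, matrix(0, 2, 10)), 0)
  E <- cbind(matrix(0, 4, 30), matrix(abs(rnorm(40)), 4, 10))
  E <- E * sqrt(0.04 / 0.96 * sum(R^2) / sum(E^2))
  M <- Wz %*% Hz + E
  expect_equal(vaf(M, Wz, Hz), 0.96, tolerance = 1e-12)
  expect_error(vaf(matrix(0, 2, 2), matrix(0, 2, 1), matrix(0, 1, 2)),
               class = "emgsynergy_degenerate")
})

test_that("multiplicative updates never increase the loss", {
  set.seed(3)
  M <- matrix(abs(rnorm(4 * 80)), 4, 80)
  for (s in 1:5) {
    fit <- nmf(M, 2L, seed = s, restarts = 1L, max_iter = 300L)
    dl <- diff(fit$loss_trace)
    expect_true(all(dl <= 1e-8 * fit$loss_trace[1]))
  }
})

test_that("planted factors are recovered up to permutation and scale", {
  t_len <- 200L
  grid <- (seq_len(t_len) - 1) / (t_len - 1)
  H0 <- rbind(exp(-0.5 * ((grid - 0.25) / 0.1)^2),
              exp(-0.5 * ((grid - 0.5) / 0.1)^2),
              exp(-0.5 * ((grid - 0.75) / 0.1)^2))
  cors <- vapply(1:20, function(s) {
    set.seed(s)
    # planted weights: structured like the generator's (distinct dominant
    # muscle per phase) with per-seed lognormal perturbation
    W0 <- default_planted_W() * matrix(exp(rnorm(12, 0, 0.15)), 4, 3)
    M <- W0 %*% H0
    M <- M + matrix(abs(rnorm(length(M), 0, 0.01 * mean(M))), nrow(M))
    fit <- nmf(M, 3L, seed = s)
    matched <- match_phases(normalize_model(fit),
                            synergy_model(W0, H0))
    mean(vapply(1:3, function(p) cor(matched$W[, p], W0[, p]), numeric(1)))
  }, numeric(1))
  expect_gte(mean(cors), 0.95)
})

test_that("order selection finds the planted rank", {
  t_len <- 120L
  grid <- (seq_len(t_len) - 1) / (t_len - 1)
  H0 <- rbind(exp(-0.5 * ((grid - 0.3) / 0.08)^2),
              exp(-0.5 * ((grid - 0.7) / 0.08)^2))
  # two distinct muscle groups so neither rank-1 factor explains both bursts
  W0 <- rbind(c(1.0, 0.1), c(0.9, 0.2), c(0.1, 1.0), c(0.2, 0.8))
  M <- W0 %*% H0
  sel <- select_order(M, vaf_threshold = 0.95, n_max = 3L, seed = 1L,
                      restarts = 5L)
  expect_identical(sel$order, 2L)
  expect_lt(sel$vaf_by_order[1], 0.95)
  expect_true(sel$reached)
  # threshold 0 accepts the first order
  sel0 <- select_order(M, vaf_threshold = 0, n_max = 3L, seed = 1L,
                       restarts = 2L)
  expect_identical(sel0$order, 1L)
  # unreachable threshold returns the best with a warning
  expect_warning(
    selu <- select_order(M + 10, vaf_threshold = 1, n_max = 2L, seed = 1L,
                         restarts = 2L),
    "reached"
  )
  expect_false(selu$reached)
})

test_that("VAF is non-decreasing in the order on planted data", {
  cfg <- synth_config()
  viol <- 0L
  total <- 0L
  for (s in 1:5) {
    cfg$seed <- s
    gen <- generate_trial(cfg, 1L)
    env <- preprocess(gen$session)
    ncs <- normalized_from_truth(gen, env)
    M <- do.call(cbind, lapply(1:4, function(k) {   # 4 cycles keep this cheap
      ncs$tensor[k, , , drop = TRUE]
    }))
    vafs <- vapply(1:4, function(n) nmf(M, n, seed = s, restarts = 5L)$vaf,
                   numeric(1))
    viol <- viol + sum(diff(vafs) < -1e-6)
    total <- total + 3L
  }
  expect_lt(viol / total, 0.05)
})

test_that("model normalization rescales rows without changing the product", {
  set.seed(5)
  W <- matrix(abs(rnorm(12)), 4, 3)
  H <- matrix(abs(rnorm(90)), 3, 30)
  H[2, ] <- H[2, ] / max(H[2, ]) * 2.5
  m <- synergy_model(W, H)
  nm <- normalize_model(m)
  expect_equal(apply(nm$H, 1, max), rep(1, 3))
  expect_equal(nm$W[, 2], W[, 2] * 2.5)
  expect_lt(max(abs(nm$W %*% nm$H - W %*% H)), 1e-9)
  expect_equal(normalize_model(nm)$H, nm$H)
  expect_error(normalize_model(synergy_model(W, H * 0)),
               class = "emgsynergy_degenerate")
})

test_that("phase matching recovers permutations", {
  set.seed(6)
  W <- matrix(abs(rnorm(12)) + 0.1, 4, 3)
  grid <- seq(0, 1, length.out = 50)
  H <- rbind(exp(-((grid - 0.2) / 0.1)^2), exp(-((grid - 0.5) / 0.1)^2),
             exp(-((grid - 0.8) / 0.1)^2))
  m <- synergy_model(W, H)
  self <- match_phases(m, m)
  expect_identical(attr(self, "permutation"), c(1, 2, 3))
  perm <- c(3, 1, 2)
  swapped <- synergy_model(W[, perm], H[perm, ])
  back <- match_phases(swapped, m)
  expect_equal(back$W, W, ignore_attr = TRUE)
  expect_equal(back$H, H, ignore_attr = TRUE)
  ref2 <- synergy_model(W[, 1:2], H[1:2, ])
  expect_error(match_phases(m, ref2), "dimensions")
})
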