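# SPAEF, permutation nulls, noise ceilings, agent-preference indices with
# the dip test, and correlation-matrix structure.

test_that("SPAEF is exactly 1 for identical maps and matches its oracle", {
  set.seed(31)
  m <- runif(36)
  s <- spaef(m, m)
  expect_identical(s$spaef, 1)
  expect_identical(c(s$A, s$B, s$C), c(1, 1, 1))
  # brute-force formula oracle on random map pairs (anti-correlated pairs
  # included via negation about the mean)
  for (i in 1:200) {
    a <- runif(36, 1, 5)
    b <- if (i %% 3 == 0) 2 * mean(a) - a + rnorm(36, 0, 0.1)
         else runif(36, 1, 5)
    expect_equal(spaef(a, b)$spaef, spaef_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("the SPAEF permutation test is calibrated", {
  set.seed(32)
  m <- runif(36)
  # identical maps: minimum attainable p
  p_id <- spaef_permutation_p(m, m, n_perm = 200, seed = 1)
  expect_identical(p_id$p, 1 / 201)
  # independent maps: p uniform (KS at 1%)
  ps <- vapply(1:300, function(i)
    spaef_permutation_p(runif(36), runif(36), n_perm = 199, seed = i)$p,
    numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # decision stability across n_perm for strongly similar maps
  noisy <- m + rnorm(36, 0, 0.05 * sd(m))
  p1 <- spaef_permutation_p(m, noisy, n_perm = 100, seed = 3)$p
  p2 <- spaef_permutation_p(m, noisy, n_perm = 1000, seed = 4)$p
  expect_identical(p1 < 0.05, p2 < 0.05)
})

test_that("noise ceilings: exact for noiseless rates, monotone in data, reproducible", {
  s <- fx_session()
  pop <- plant_tuned_neurons(list("self", "self"),
                             variables = c("self", "chosen_prey"),
                             bump_log_height = log(6), seed = 8)
  # deterministic 'counts' = expected counts (no Poisson draw)
  b_all <- bin_position(s, "self", trial_filter = NULL)
  lam <- matrix(0, s$n_frames, 2)
  for (i in 1:2) {
    w <- pop$weights$self[i, ]
    ok <- !is.na(b_all$bin)
    lam[ok, i] <- pop$baseline_hz[i] * exp(w[b_all$bin[ok]]) / 60
    lam[!ok, i] <- pop$baseline_hz[i] / 60
  }
  attr(lam, "frame_dt") <- 1 / 60
  nc <- spaef_noise_ceiling(s, lam, "self", n_splits = 15, seed = 2)
  expect_gt(nc$population_mean, 0.9)
  # reproducibility
  nc2 <- spaef_noise_ceiling(s, lam, "self", n_splits = 15, seed = 2)
  expect_identical(nc$per_neuron, nc2$per_neuron)
  # Poisson neuron: ceiling grows with session length
  s_long <- simulate_session(task_config(), 50, seed = 43)
  short_ids <- s_long$trials$trial_id[1:10]
  spk <- simulate_spikes(s_long, pop, seed = 9)
  s_short <- s_long
  s_short$trials <- s_long$trials[s_long$trials$trial_id %in% short_ids, ]
  c_short <- spaef_noise_ceiling(s_short, spk, "self", n_splits = 25,
                                 seed = 3)$population_mean
  c_long <- spaef_noise_ceiling(s_long, spk, "self", n_splits = 25,
                                seed = 3)$population_mean
  expect_gt(c_long, c_short)
})

test_that("the dip statistic hits its exact anchors and scales", {
  expect_identical(dip_statistic(1:100), 1 / 200)    # unimodally fittable
  expect_identical(dip_statistic(seq(0, 1, length.out = 8)), 1 / 16)
  expect_identical(dip_statistic(rep(c(0, 1), each = 100)), 0.25) # max dip
  expect_identical(dip_statistic(c(2, 2, 2)), 0)     # degenerate
  # shift/scale invariance
  set.seed(33)
  x <- rnorm(150)
  expect_equal(dip_statistic(x), dip_statistic(5 * x - 3), tolerance = 1e-12)
})

test_that("the dip test keeps type-I error and detects strong bimodality", {
  set.seed(34)
  null <- dip_null_distribution(200, n_boot = 2000, seed = 1)
  crit <- quantile(null, 0.95)
  rej <- mean(vapply(1:500, function(i)
    dip_statistic(rnorm(200)) > crit, logical(1)))
  expect_lte(rej, 0.07)
  # clear bimodality at N=200 rejects
  xb <- c(rnorm(100, -2), rnorm(100, 2))
  expect_lt(dip_test(xb, n_boot = 2000, seed = 1)$p_value, 0.05)
})

test_that("agent-preference indices are antisymmetric with a calibrated dip", {
  pms <- fx_pms()
  ab <- agent_preference_indices(pms$self, pms$chosen_prey, n_boot = 500,
                                 seed = 2)
  ba <- agent_preference_indices(pms$chosen_prey, pms$self, n_boot = 500,
                                 seed = 2)
  expect_equal(ab$api, -ba$api)
  # equal-strength population: all api zero
  pm <- pms$self
  expect_true(all(abs(agent_preference_indices(pm, pm, n_boot = 500,
                                               seed = 3)$api) < 1e-12))
  # segregated pools (ranges ~10:1) give a bimodal api distribution
  set.seed(35)
  n <- 200
  big <- matrix(runif(n / 2 * 36, 0, 10), n / 2)
  small <- matrix(runif(n / 2 * 36, 0, 1), n / 2)
  pa <- build_population_matrix(rbind(big, small))
  pb <- build_population_matrix(rbind(small, big))
  res <- agent_preference_indices(pa, pb, n_boot = 1000, seed = 4)
  expect_lt(res$dip_p, 0.05)
  # one mixed-selective pool stays unimodal
  mixed_a <- build_population_matrix(matrix(runif(n * 36, 0, 5), n))
  mixed_b <- build_population_matrix(matrix(runif(n * 36, 0, 5), n))
  res2 <- agent_preference_indices(mixed_a, mixed_b, n_boot = 1000, seed = 5)
  expect_gt(res2$dip_p, 0.05)
})

test_that("correlation structure compares matrices over a shared neuron order", {
  pms <- fx_pms()
  cs <- correlation_structure(pms[c("self", "chosen_prey")])
  expect_true(isSymmetric(cs$C$self))
  expect_equal(diag(cs$C$self), rep(1, nrow(cs$C$self)))
  expect_identical(sort(cs$leaf_order), seq_len(nrow(cs$C$self)))
  # identical inputs: r2 = 1
  cs2 <- correlation_structure(list(a = pms$self, b = pms$self))
  expect_equal(cs2$cross_r2["a", "b"], 1)
  # independent random populations: r2 near zero
  set.seed(36)
  pa <- build_population_matrix(matrix(rnorm(100 * 36), 100))
  pb <- build_population_matrix(matrix(rnorm(100 * 36), 100))
  cs3 <- correlation_structure(list(a = pa, b = pb))
  expect_lt(cs3$cross_r2["a", "b"], 0.01)
  # permuting neurons leaves the cross-matrix r2 unchanged
  perm <- sample(100)
  pa2 <- build_population_matrix(pa$raw[perm, , drop = FALSE])
  pb2 <- build_population_matrix(pb$raw[perm, , drop = FALSE])
  cs4 <- correlation_structure(list(a = pa2, b = pb2))
  expect_equal(cs4$cross_r2["a", "b"], cs3$cross_r2["a", "b"])
  expect_error(correlation_structure(
    list(a = pa, b = build_population_matrix(pb$raw[1:50, ]))),
    "mismatched")
})
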