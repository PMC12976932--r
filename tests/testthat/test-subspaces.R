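# Population-subspace geometry: PCA cross-variance, alignment index,
# covariance splits, Stiefel optimization, cross-projections, linear maps.

test_that("PCA cross-variance matches planted constructions", {
  p <- plant_population(60, map_noise_sd = 0.05, seed = 61)
  M <- p$weights$self
  pc <- pca_cross_variance(M, list(self = M), k = 10)
  expect_equal(unname(pc$var_explained_other["self"]),
               pc$var_explained_ref)
  # other variable built in the orthogonal complement of the reference
  p90 <- plant_population(60, angles_deg = c(chosen_prey = 90), seed = 62)
  pc90 <- pca_cross_variance(p90$weights$self,
                             list(o = p90$weights$chosen_prey), k = 4)
  expect_lt(pc90$var_explained_other["o"], 1e-6)
  # balanced mix: half the variance in the reference subspace
  A2 <- p90$geometry$A$chosen_prey
  M_mix <- (p90$geometry$Q$self %*% p90$geometry$A$self +
            p90$geometry$Q$chosen_prey %*% A2) / sqrt(2)
  pc_mix <- pca_cross_variance(p90$weights$self, list(m = M_mix), k = 4)
  expect_lt(abs(pc_mix$var_explained_other["m"] - 0.5), 0.05)
})

test_that("alignment index hits its exact anchors and planted angles", {
  p <- plant_population(60, map_noise_sd = 0.1, seed = 63)
  M <- build_population_matrix(p$weights$self)
  res <- alignment_index(M, M, k = 10, n_null = 100, seed = 1)
  expect_equal(res$ai, 1)
  expect_true(all(res$null >= 0 & res$null <= 1 + 1e-9))
  # noiseless: AI = cos^2(theta) to 1e-6
  for (th in c(0, 30, 60, 90)) {
    pth <- plant_population(80, angles_deg = c(chosen_prey = th), seed = th + 1)
    ai <- alignment_index(pth$weights$self, pth$weights$chosen_prey,
                          k = 4, n_null = 0)$ai
    expect_lt(abs(ai - cos(th * pi / 180)^2), 1e-6)
  }
  # with noise at SNR >= 10: within 0.05
  for (th in c(0, 30, 60, 90)) {
    pth <- plant_population(120, angles_deg = c(chosen_prey = th),
                            latent_sd = 0.4, map_noise_sd = 0.01,
                            seed = th + 7)
    ai <- alignment_index(pth$weights$self, pth$weights$chosen_prey,
                          k = 4, n_null = 0)$ai
    expect_lt(abs(ai - cos(th * pi / 180)^2), 0.05)
  }
  # invariance to a joint neuron permutation
  set.seed(64)
  perm <- sample(60)
  ai_1 <- alignment_index(p$weights$self, p$weights$chosen_prey,
                          k = 4, n_null = 0)$ai
  ai_2 <- alignment_index(p$weights$self[perm, ],
                          p$weights$chosen_prey[perm, ],
                          k = 4, n_null = 0)$ai
  expect_equal(ai_1, ai_2)
  expect_error(alignment_index(p$weights$self[1:8, ],
                               p$weights$chosen_prey[1:8, ], k = 10),
               "N > k")
})

test_that("half-split covariance correlation separates shared from independent maps", {
  s <- fx_session()
  pop <- plant_population(60, variables = c("self", "chosen_prey",
                                            "unchosen_prey"),
                          angles_deg = c(chosen_prey = 60,
                                         unchosen_prey = 90),
                          latent_sd = 0.8, baseline_hz = c(8, 20), seed = 77)
  spk <- simulate_spikes(s, pop, seed = 77)
  # a variable against itself: exact ties, p near 0.5
  r_self <- covariance_split_correlation(s, spk, "self", "self",
                                         n_iter = 40, seed = 1)
  expect_equal(r_self$r2_cross, r_self$r2_within_floor)
  expect_gt(r_self$p, 0.2); expect_lt(r_self$p, 0.8)
  # independent planted maps on behaviourally decorrelated variables:
  # cross below within
  r_ind <- covariance_split_correlation(s, spk, "self", "unchosen_prey",
                                        n_iter = 60, seed = 2)
  expect_lt(r_ind$r_cross, r_ind$r_within)
  expect_lt(r_ind$p, 0.05)
})

test_that("the Stiefel optimizer meets its constraints and anchors", {
  p <- plant_population(80, angles_deg = c(chosen_prey = 90),
                        map_noise_sd = 0.02, seed = 65)
  Cs <- lapply(p$weights, pursuitgeom:::neuron_cov)
  b <- optimize_orthogonal_subspaces(Cs, d_list = 4, n_starts = 3, seed = 1)
  expect_lt(max(abs(crossprod(b$Q$self) - diag(4))), 1e-8)
  expect_lt(max(abs(crossprod(b$Q$chosen_prey) - diag(4))), 1e-8)
  expect_lt(max(abs(crossprod(b$Q$self, b$Q$chosen_prey))), 1e-8)
  expect_true(all(diff(b$trace) >= -1e-12))
  # orthogonal planted structure is fully recoverable
  expect_true(all(b$var_captured > 0.99))
  # V = 1: the top-d eigenspace, objective 1
  b1 <- optimize_orthogonal_subspaces(Cs[1], d_list = 4, n_starts = 2,
                                      seed = 2)
  expect_equal(b1$objective, 1, tolerance = 1e-6)
  ev <- eigen(Cs[[1]], symmetric = TRUE)$vectors[, 1:4]
  proj <- b1$Q[[1]] - ev %*% crossprod(ev, b1$Q[[1]])
  expect_lt(max(abs(proj)), 1e-4)
  # collinear variables: the orthogonality constraint must cost variance
  bc <- optimize_orthogonal_subspaces(list(a = Cs[[1]], b = Cs[[1]]),
                                      d_list = 4, n_starts = 3, seed = 3)
  expect_lt(sum(bc$var_captured), 2 * b1$objective - 0.05)
})

test_that("cross-projection fractions separate planted orthogonal variables", {
  p <- plant_population(80, angles_deg = c(chosen_prey = 90),
                        map_noise_sd = 0.02, seed = 66)
  Cs <- lapply(p$weights, pursuitgeom:::neuron_cov)
  b <- optimize_orthogonal_subspaces(Cs, d_list = 4, n_starts = 3, seed = 1)
  cp <- cross_projection_variance(p$weights, b, n_boot = 100, seed = 2)
  expect_equal(unname(diag(cp$fractions)), unname(b$var_captured),
               tolerance = 1e-10)
  expect_lt(cp$fractions["self", "chosen_prey"], 0.05)
  expect_lt(cp$fractions["chosen_prey", "self"], 0.05)
  expect_true(all(cp$p[!is.na(cp$p)] < 0.05))
  # span invariance: permuting basis columns changes nothing
  b2 <- b; b2$Q <- lapply(b$Q, function(Q) Q[, c(3, 1, 4, 2)])
  cp2 <- cross_projection_variance(p$weights, b2, n_boot = 0)
  expect_equal(cp2$fractions, cp$fractions)
})

test_that("linear maps recover planted transformations and their nulls", {
  set.seed(67)
  Xa <- matrix(rnorm(4 * 36), 4)
  W_true <- matrix(rnorm(16), 4)
  f <- fit_linear_map(Xa, W_true %*% Xa, n_shuffle = 100, seed = 1)
  expect_equal(f$r2_train, 1, tolerance = 1e-12)
  expect_equal(f$r2_loocv, 1, tolerance = 1e-10)
  expect_lt(max(abs(f$W - W_true)), 1e-9)
  expect_lt(f$p, 0.05)
  # 10% noise: relative Frobenius error < 0.2
  Xb <- W_true %*% Xa
  Xb_n <- Xb + matrix(rnorm(length(Xb), 0, 0.1 * sd(Xb)), nrow(Xb))
  fn <- fit_linear_map(Xa, Xb_n, n_shuffle = 0)
  expect_lt(sqrt(sum((fn$W - W_true)^2)) / sqrt(sum(W_true^2)), 0.2)
  # independent target: no transfer, p large
  f0 <- fit_linear_map(Xa, matrix(rnorm(4 * 36), 4), n_shuffle = 200,
                       seed = 2)
  expect_lt(f0$r2_loocv, 0.2)
  expect_gt(f0$p, 0.05)
  # rank-deficient predictors are flagged
  Xa_def <- rbind(Xa[1:3, ], Xa[3, ])
  expect_true(fit_linear_map(Xa_def, Xb, n_shuffle = 0)$rank_deficient)
})

test_that("the leverage LOOCV equals a brute-force refit loop", {
  set.seed(68)
  for (rep in 1:5) {
    Xa <- matrix(rnorm(4 * 36), 4)
    Xb <- matrix(rnorm(16), 4) %*% Xa + matrix(rnorm(4 * 36, 0, 0.3), 4)
    got <- fit_linear_map(Xa, Xb, n_shuffle = 0)$r2_loocv
    press <- 0
    for (c_ in 1:36) {
      A <- Xa[, -c_]; B <- Xb[, -c_]
      Wc <- B %*% t(A) %*% solve(A %*% t(A))
      press <- press + sum((Xb[, c_] - Wc %*% Xa[, c_, drop = FALSE])^2)
    }
    expect_equal(got, 1 - press / sum(Xb^2), tolerance = 1e-12)
  }
})
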