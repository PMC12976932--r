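# Task simulator and ground-truth population generator.

test_that("sessions are bit-reproducible under a fixed seed", {
  s1 <- simulate_session(task_config(), 5, seed = 7)
  s2 <- simulate_session(task_config(), 5, seed = 7)
  expect_identical(s1, s2)
  pop <- plant_population(8, seed = 7)
  expect_identical(simulate_spikes(s1, pop, seed = 3),
                   simulate_spikes(s2, pop, seed = 3))
})

test_that("trajectories respect the speed cap and field bounds", {
  s <- fx_session()
  cfg <- s$config
  for (v in names(s$traj)) {
    tr <- s$traj[[v]]
    ok <- tr$valid
    expect_true(all(tr$x[ok] >= 0 & tr$x[ok] <= cfg$field_width))
    expect_true(all(tr$y[ok] >= 0 & tr$y[ok] <= cfg$field_height))
  }
  step <- sqrt(diff(s$traj$self$x)^2 + diff(s$traj$self$y)^2)
  step <- step[!is.na(step)]
  expect_true(all(step <= cfg$avatar_max_speed + 1e-9))
})

test_that("trial records are consistent and capture is non-trivial", {
  s <- fx_session()
  tt <- s$trials
  expect_true(all(tt$start_frame < tt$end_frame))
  max_s <- s$config$trial_timeout + s$config$frame_dt
  expect_true(all((tt$end_frame - tt$start_frame) * s$config$frame_dt
                  <= max_s))
  frac <- mean(tt$outcome == "captured")
  expect_gt(frac, 0)
  expect_lt(frac, 1)
  s1 <- simulate_session(task_config(), 1, seed = 3)
  expect_identical(nrow(s1$trials), 1L)
})

test_that("a predator one step away captures a frozen avatar", {
  # single-step geometry: predator 10 px from the avatar moving at 23
  # px/frame lands on it; distance 0 <= threshold 22.5
  cfg <- task_config(predator_enabled = TRUE, predator_speed = 23,
                     n_prey = 1,
                     init_positions = list(self = c(900, 500),
                                           predator = c(910, 500)))
  r <- simulate_trial(cfg, policy = "frozen", seed = 1)
  expect_identical(r$record$outcome, "caught_by_predator")
  expect_identical(r$record$n_frames, 2L)
})

test_that("with repulsion disabled the prey drifts to the field center", {
  # cost cutoff above the sigmoid maximum (1) disables repulsion entirely
  cfg <- task_config(n_prey = 1, repulsion_cutoff = 2, trial_timeout = 10)
  r <- simulate_trial(cfg, policy = "frozen", seed = 5)
  prey <- r$trajectories$prey1
  ctr <- c(900, 500)
  d_first <- sqrt(sum((prey[1, ] - ctr)^2))
  d_last <- sqrt(sum((prey[nrow(prey), ] - ctr)^2))
  expect_lt(d_last, d_first / 4)
})

test_that("initial avatar-prey separation honours the minimum", {
  for (seed in 1:5) {
    r <- simulate_trial(task_config(), seed = seed)
    d0 <- sqrt(sum((r$trajectories$prey1[1, ] - r$trajectories$self[1, ])^2))
    expect_gte(d0, 400)
  }
})

test_that("planted principal angles and subspaces match the request", {
  for (th in c(0, 30, 60, 90)) {
    p <- plant_population(40, angles_deg = c(chosen_prey = th), seed = 11)
    expect_lt(max(abs(planted_angles(p, "self", "chosen_prey") - th)), 1e-6)
  }
  # 0 degrees: identical spans (projection residual ~ 0)
  p0 <- plant_population(40, angles_deg = c(chosen_prey = 0), seed = 12)
  Qa <- p0$geometry$Q$self; Qb <- p0$geometry$Q$chosen_prey
  resid <- Qb - Qa %*% crossprod(Qa, Qb)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("a planted linear map is recovered exactly from the latents", {
  W <- 2 * diag(4)
  p <- plant_population(40, linear_map = list(from = "self",
                                              to = "chosen_prey", W = W),
                        seed = 13)
  A <- p$geometry$A
  W_hat <- A$chosen_prey %*% t(A$self) %*% solve(tcrossprod(A$self))
  expect_lt(max(abs(W_hat - W)), 1e-9)
})

test_that("inverted axis relation plants an exact sign flip", {
  p <- plant_population(40, variables = c("self", "chosen_prey"),
                        axis_relations = c(chosen_prey = "inverted"),
                        axis_strength = 0.3, seed = 14)
  ax <- p$geometry$axes
  expect_equal(ax[, "chosen_prey"], -ax[, "self"])
})

test_that("constant-rate neurons obey the Poisson law", {
  n <- 12000 # frames
  s <- make_const_session(n)
  pop <- plant_tuned_neurons(list(character(0), character(0)),
                             baseline_hz = c(5, 5), seed = 3)
  pop$baseline_hz[] <- 5
  spk <- simulate_spikes(s, pop, seed = 9)
  dt <- 1 / 60
  # mean rate 5 Hz within 3 SE
  se <- sqrt(5 / (n * dt))
  expect_lt(abs(mean(spk[, 1]) / dt - 5), 3 * se)
  # variance/mean ratio near 1
  expect_gt(var(spk[, 1]) / mean(spk[, 1]), 0.8)
  expect_lt(var(spk[, 1]) / mean(spk[, 1]), 1.2)
})

test_that("a single hot bin drives the empirical rate in that bin", {
  set.seed(21)
  n <- 40000
  # random walk over bins so every bin gets visits
  s <- make_const_session(n, pos = function(f)
    cbind(runif(length(f), 0, 1800), runif(length(f), 0, 1000)),
    variables = "self")
  pop <- plant_tuned_neurons(list("self"), variables = "self",
                             bump_log_height = log(10),
                             bump_sd_bins = 0.5, seed = 4)
  spk <- simulate_spikes(s, pop, seed = 5)
  b <- bin_position(s, "self")
  expect_true(all(tabulate(b$bin, 36) >= 200))
  rm0 <- compute_rate_map(spk[, 1], b, 1 / 60, smoothing_sd = 0)
  hot <- which.max(pop$weights$self[1, ])
  expect_identical(which.max(rm0$values), hot)
})

test_that("zero-length sessions give an empty spike matrix", {
  s <- make_const_session(1)
  s$n_frames <- 0L
  s$traj <- lapply(s$traj, function(t) list(x = numeric(0), y = numeric(0),
                                            valid = logical(0)))
  pop <- plant_tuned_neurons(list(character(0)), seed = 1)
  spk <- simulate_spikes(s, pop, seed = 1)
  expect_identical(dim(spk), c(0L, 1L))
})

test_that("gaze follows its target, drops out, and tracks the prey", {
  s <- fx_session()
  g1 <- simulate_gaze(s, c(self = 1), jitter_sd = 0, dropout_prob = 0,
                      seed = 2)
  ok <- g1$traj$gaze$valid
  expect_true(any(ok))
  expect_equal(g1$traj$gaze$x[ok], g1$traj$self$x[ok])
  g2 <- simulate_gaze(s, c(self = 1), dropout_prob = 1, seed = 2)
  expect_false(any(g2$traj$gaze$valid))
  g3 <- simulate_gaze(s, c(chosen_prey = 1), jitter_sd = 20,
                      dropout_prob = 0, seed = 3)
  ok <- g3$traj$gaze$valid & g3$traj$self$valid
  d_prey <- sqrt((g3$traj$gaze$x[ok] - g3$traj$chosen_prey$x[ok])^2 +
                 (g3$traj$gaze$y[ok] - g3$traj$chosen_prey$y[ok])^2)
  d_self <- sqrt((g3$traj$gaze$x[ok] - g3$traj$self$x[ok])^2 +
                 (g3$traj$gaze$y[ok] - g3$traj$self$y[ok])^2)
  expect_lt(median(d_prey), median(d_self))
})
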