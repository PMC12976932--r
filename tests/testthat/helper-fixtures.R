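# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; no data files.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small default session: ~25 trials, two prey.
fx_session <- function() fx("session", function() {
  simulate_session(task_config(), 25, seed = 42)
})

# Geometry population on the small session's variables, with mild noise.
fx_pop <- function() fx("pop", function() {
  plant_population(30, variables = c("self", "chosen_prey", "unchosen_prey"),
                   angles_deg = c(chosen_prey = 60, unchosen_prey = 90),
                   latent_sd = 0.45, seed = 42)
})

fx_spikes <- function() fx("spikes", function() {
  simulate_spikes(fx_session(), fx_pop(), seed = 42)
})

fx_pms <- function() fx("pms", function() {
  population_matrices(fx_session(), fx_spikes(),
                      c("self", "chosen_prey", "unchosen_prey"))
})

# A minimal hand-built session: one captured trial of n_frames frames with
# every variable valid and positions supplied by `pos` (a function of frame
# index returning cbind(x, y)), at 60 Hz. Used where exact durations or
# occupancies matter.
make_const_session <- function(n_frames, pos = NULL,
                               variables = c("self", "chosen_prey")) {
  if (is.null(pos)) pos <- function(f) cbind(900, 500)
  xy <- pos(seq_len(n_frames))
  traj <- lapply(variables, function(v)
    list(x = rep_len(xy[, 1], n_frames), y = rep_len(xy[, 2], n_frames),
         valid = rep(TRUE, n_frames)))
  names(traj) <- variables
  structure(list(
    config = task_config(), frame_dt = 1 / 60, n_frames = n_frames,
    t_s = (seq_len(n_frames) - 1) / 60, traj = traj,
    trials = data.frame(trial_id = 1L, start_frame = 1L,
                        end_frame = n_frames, outcome = "captured",
                        chosen_prey_id = 1L, reward = 1L)
  ), class = "pursuit_session")
}

# Independent brute-force SPAEF oracle: different code path (cut() based
# histograms, explicit formulas) from the implementation.
spaef_oracle <- function(a, b, hist_bins = 10) {
  A <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  cv <- function(x) stats::sd(x) / mean(x)
  B <- cv(b) / cv(a)
  za <- (a - mean(a)) / stats::sd(a)
  zb <- (b - mean(b)) / stats::sd(b)
  br <- seq(min(c(za, zb)), max(c(za, zb)), length.out = hist_bins + 1)
  ha <- table(cut(za, br, include.lowest = TRUE))
  hb <- table(cut(zb, br, include.lowest = TRUE))
  C <- sum(pmin(ha, hb)) / sum(ha)
  1 - sqrt((A - 1)^2 + (B - 1)^2 + (C - 1)^2)
}

# Brute-force mass-preserving truncated-Gaussian smoother: per-source
# normalized scatter, written as explicit loops.
smooth_oracle <- function(map, sigma) {
  g <- spatial_grid()
  out <- rep(0, 36)
  for (s in 1:36) {
    sr <- (s - 1) %/% 6 + 1; sc <- (s - 1) %% 6 + 1
    w <- rep(0, 36)
    for (t in 1:36) {
      tr <- (t - 1) %/% 6 + 1; tc <- (t - 1) %% 6 + 1
      w[t] <- exp(-((sr - tr)^2 + (sc - tc)^2) / (2 * sigma^2))
    }
    out <- out + map[s] * w / sum(w)
  }
  out
}

# Evaluate expr under a local seed without disturbing the global stream.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
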