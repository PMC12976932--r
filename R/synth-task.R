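#' Task configuration for the pursuit simulator
#'
#' Parameters of the simulated prey-pursuit task: a joystick avatar chases one
#' or two prey on a 1800 x 1000 px screen at 60 Hz, prey move by minimum-cost
#' selection over 15 candidate positions (a center-bias cost plus a sigmoidal
#' avatar-repulsion cost), an optional predator homes in on the avatar at
#' constant speed, and a trial ends at capture or after 20 s.
#'
#' Capture is declared when the avatar-prey center distance falls below
#' `capture_threshold` (default 22.5 px = avatar radius 7.5 + prey half-side
#' 15, a monotone proxy for circle-square tangency). `capture_rule =
#' "tangency"` instead tests exact overlap between the avatar circle and the
#' axis-aligned prey square.
#'
#' @param field_width,field_height Screen size in pixels.
#' @param frame_dt Frame duration in seconds (60 Hz).
#' @param avatar_max_speed Avatar speed cap, px/frame.
#' @param prey_max_speed Prey speed, px/frame; recycled over prey.
#' @param n_prey Number of prey (1 or 2).
#' @param predator_enabled,predator_speed Predator presence and speed.
#' @param trial_timeout Trial time limit, seconds.
#' @param min_initial_separation Minimum avatar-prey spawn distance, px.
#' @param avatar_radius,prey_half_side Agent geometry, px.
#' @param capture_rule `"center_distance"` or `"tangency"`.
#' @param capture_threshold Center-distance capture threshold, px.
#' @param center_bias_strength Gain of the quadratic center-bias cost.
#' @param repulsion_midpoint,repulsion_slope,repulsion_cutoff Sigmoid
#'   avatar-repulsion cost: midpoint (px), slope (1/px), and the cost level
#'   below which repulsion is treated as exactly zero.
#' @param policy_kappa Von Mises concentration of the pursuit-policy heading
#'   noise (larger = straighter pursuit).
#' @param policy_speed_range Range of the per-frame multiplicative speed
#'   jitter of the pursuit policy.
#' @param inter_trial_gap_frames Invalid frames inserted between trials when
#'   concatenating a session.
#' @param init_positions Optional named list of spawn overrides, e.g.
#'   `list(self = c(900, 500), prey1 = c(900, 900), predator = c(50, 50))`.
#' @return A `"task_config"` list.
#' @export
task_config <- function(field_width = 1800, field_height = 1000,
                        frame_dt = 1 / 60,
                        avatar_max_speed = 23,
                        prey_max_speed = 17,
                        n_prey = 2,
                        predator_enabled = FALSE, predator_speed = 11,
                        trial_timeout = 20,
                        min_initial_separation = 400,
                        avatar_radius = 7.5, prey_half_side = 15,
                        capture_rule = c("center_distance", "tangency"),
                        capture_threshold = avatar_radius + prey_half_side,
                        center_bias_strength = 0.5,
                        repulsion_midpoint = 200, repulsion_slope = 0.02,
                        repulsion_cutoff = 1e-3,
                        policy_kappa = 3.5, policy_speed_range = c(0.75, 1),
                        inter_trial_gap_frames = 30,
                        init_positions = NULL) {
  capture_rule <- match.arg(capture_rule)
  cfg <- as.list(environment())
  cfg$prey_max_speed <- rep_len(prey_max_speed, n_prey)
  stopifnot(
    cfg$frame_dt > 0, cfg$trial_timeout > 0,
    cfg$avatar_max_speed > 0, all(cfg$prey_max_speed > 0),
    cfg$predator_speed > 0, cfg$n_prey %in% 1:2,
    cfg$min_initial_separation < min(field_width, field_height),
    cfg$capture_threshold > 0
  )
  structure(cfg, class = "task_config")
}

clip_xy <- function(p, cfg) {
  c(min(max(p[1], 0), cfg$field_width), min(max(p[2], 0), cfg$field_height))
}

# Von Mises draw via Best & Fisher rejection; vectorized draws not needed.
rvm1 <- function(mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(1, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (u[2] < c_ * (2 - c_) || log(c_ / u[2]) + 1 - c_ >= 0) {
      th <- if (u[3] > 0.5) acos(f) else -acos(f)
      return((mu + th + pi) %% (2 * pi) - pi)
    }
  }
}

# Cost of candidate prey positions (vectorized over rows of pos):
# quadratic center bias plus sigmoidal avatar repulsion, zeroed below the
# cost cutoff.
prey_cost <- function(pos, avatar, cfg) {
  half_diag <- sqrt(cfg$field_width^2 + cfg$field_height^2) / 2
  cx <- cfg$field_width / 2; cy <- cfg$field_height / 2
  d_ctr2 <- (pos[, 1] - cx)^2 + (pos[, 2] - cy)^2
  cost <- cfg$center_bias_strength * d_ctr2 / half_diag^2
  d_av <- sqrt((pos[, 1] - avatar[1])^2 + (pos[, 2] - avatar[2])^2)
  rep_cost <- 1 / (1 + exp(cfg$repulsion_slope * (d_av - cfg$repulsion_midpoint)))
  cost + ifelse(rep_cost >= cfg$repulsion_cutoff, rep_cost, 0)
}

# One prey step: argmin over 15 candidates on the max-step circle, skipping
# off-screen candidates in ascending cost order.
prey_step <- function(pos, avatar, speed, cfg) {
  ang <- 2 * pi * (0:14) / 15
  cand <- cbind(pos[1] + speed * cos(ang), pos[2] + speed * sin(ang))
  costs <- prey_cost(cand, avatar, cfg)
  inb <- cand[, 1] >= 0 & cand[, 1] <= cfg$field_width &
    cand[, 2] >= 0 & cand[, 2] <= cfg$field_height
  if (!any(inb)) return(pos) # cannot happen on a convex field; safety
  keep <- which(inb)
  cand[keep[which.min(costs[keep])], ]
}

step_toward <- function(from, to, speed, cfg) {
  d <- sqrt(sum((to - from)^2))
  if (d <= speed) return(clip_xy(to, cfg))
  clip_xy(from + (to - from) * speed / d, cfg)
}

captured <- function(avatar, prey, cfg) {
  if (cfg$capture_rule == "center_distance") {
    sqrt(sum((avatar - prey)^2)) <= cfg$capture_threshold
  } else {
    # circle vs axis-aligned square overlap
    dx <- max(abs(avatar[1] - prey[1]) - cfg$prey_half_side, 0)
    dy <- max(abs(avatar[2] - prey[2]) - cfg$prey_half_side, 0)
    sqrt(dx^2 + dy^2) <= cfg$avatar_radius
  }
}

spawn_positions <- function(cfg) {
  ctr <- c(cfg$field_width, cfg$field_height) / 2
  self <- cfg$init_positions$self %||% ctr
  margin <- 100
  cardinal <- list(
    c(cfg$field_width / 2, cfg$field_height - margin),
    c(cfg$field_width / 2, margin),
    c(margin, cfg$field_height / 2),
    c(cfg$field_width - margin, cfg$field_height / 2)
  )
  ok <- vapply(cardinal, function(p)
    sqrt(sum((p - self)^2)) >= cfg$min_initial_separation, logical(1))
  if (sum(ok) < cfg$n_prey)
    stop("generation error: cannot place ", cfg$n_prey,
         " prey >= min_initial_separation from the avatar")
  picks <- sample(which(ok), cfg$n_prey)
  prey <- lapply(picks, function(i) cardinal[[i]])
  for (k in seq_len(cfg$n_prey)) {
    ov <- cfg$init_positions[[paste0("prey", k)]]
    if (!is.null(ov)) prey[[k]] <- ov
  }
  pred <- NULL
  if (cfg$predator_enabled) {
    corners <- list(c(50, 50), c(cfg$field_width - 50, 50),
                    c(50, cfg$field_height - 50),
                    c(cfg$field_width - 50, cfg$field_height - 50))
    okc <- vapply(corners, function(p)
      sqrt(sum((p - self)^2)) >= cfg$min_initial_separation, logical(1))
    if (!any(okc)) stop("generation error: cannot place predator")
    pred <- cfg$init_positions$predator %||% corners[[sample(which(okc), 1)]]
  }
  list(self = self, prey = prey, predator = pred)
}

#' Simulate one pursuit trial
#'
#' Runs the frame-by-frame task dynamics under a built-in avatar policy and
#' returns per-agent trajectories plus a trial record. The `"pursuit"` policy
#' heads toward the target prey (nearest at trial start) at the speed cap with
#' von Mises heading noise and multiplicative speed jitter; `"frozen"` keeps
#' the avatar still (useful for probing the prey cost field).
#'
#' @param config A [task_config()].
#' @param policy `"pursuit"` or `"frozen"`.
#' @param seed Integer seed; the trial is a pure function of `(config,
#'   policy, seed)`.
#' @return A list with `trajectories` (named list of `frames x 2` position
#'   matrices: `self`, `prey1`, ..., optionally `predator`) and `record`
#'   (one-row data frame: outcome, chosen prey, reward, frame count).
#' @export
simulate_trial <- function(config, policy = c("pursuit", "frozen"), seed = 1) {
  policy <- match.arg(policy)
  cfg <- config
  with_seed(seed, {
    sp <- spawn_positions(cfg)
    n_max <- as.integer(round(cfg$trial_timeout / cfg$frame_dt))
    agents <- c("self", paste0("prey", seq_len(cfg$n_prey)),
                if (cfg$predator_enabled) "predator")
    pos <- c(list(self = sp$self),
             stats::setNames(sp$prey, paste0("prey", seq_len(cfg$n_prey))),
             if (cfg$predator_enabled) list(predator = sp$predator))
    traj <- lapply(agents, function(a)
      matrix(NA_real_, n_max + 1L, 2, dimnames = list(NULL, c("x", "y"))))
    names(traj) <- agents
    for (a in agents) traj[[a]][1, ] <- pos[[a]]

    d0 <- vapply(seq_len(cfg$n_prey),
                 function(k) sqrt(sum((pos[[paste0("prey", k)]] - pos$self)^2)),
                 numeric(1))
    target <- which.min(d0)
    outcome <- "timeout"; cap_prey <- NA_integer_; last <- n_max + 1L

    for (f in seq_len(n_max) + 1L) {
      if (policy == "pursuit") {
        tgt <- pos[[paste0("prey", target)]]
        mu <- atan2(tgt[2] - pos$self[2], tgt[1] - pos$self[1])
        th <- rvm1(mu, cfg$policy_kappa)
        sp_f <- cfg$avatar_max_speed *
          stats::runif(1, cfg$policy_speed_range[1], cfg$policy_speed_range[2])
        step <- min(sp_f, sqrt(sum((tgt - pos$self)^2)))
        pos$self <- clip_xy(pos$self + step * c(cos(th), sin(th)), cfg)
      }
      for (k in seq_len(cfg$n_prey)) {
        nm <- paste0("prey", k)
        pos[[nm]] <- prey_step(pos[[nm]], pos$self, cfg$prey_max_speed[k], cfg)
      }
      if (cfg$predator_enabled)
        pos$predator <- step_toward(pos$predator, pos$self,
                                    cfg$predator_speed, cfg)
      for (a in agents) traj[[a]][f, ] <- pos[[a]]

      hit <- which(vapply(seq_len(cfg$n_prey), function(k)
        captured(pos$self, pos[[paste0("prey", k)]], cfg), logical(1)))
      if (length(hit)) {
        outcome <- "captured"; cap_prey <- hit[1]; last <- f; break
      }
      if (cfg$predator_enabled &&
          sqrt(sum((pos$predator - pos$self)^2)) <= cfg$capture_threshold) {
        outcome <- "caught_by_predator"; last <- f; break
      }
    }
    traj <- lapply(traj, function(m) m[seq_len(last), , drop = FALSE])
    chosen <- if (!is.na(cap_prey)) cap_prey else target
    reward <- if (outcome == "captured") sample(1:5, 1) else 0L
    list(
      trajectories = traj,
      record = data.frame(
        outcome = outcome, chosen_prey_id = chosen, reward = reward,
        n_frames = last, stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate a full session
#'
#' Concatenates `n_trials` independently seeded trials into one continuous
#' frame base, inserting `inter_trial_gap_frames` invalid frames between
#' trials. Prey trajectories are relabelled per trial into `chosen_prey` /
#' `unchosen_prey` using the trial's captured (or, on timeout, pursued) prey.
#' Each trial draws from its own child random stream, so sessions are
#' bit-reproducible and extending `n_trials` never alters earlier trials.
#'
#' @param config A [task_config()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Root seed.
#' @param policy Avatar policy passed to [simulate_trial()].
#' @return A `"pursuit_session"` object: `frame_dt`, `n_frames`, `t_s`,
#'   `traj` (named list with `x`, `y`, `valid` per variable), and `trials`
#'   (data frame with start/end frames, outcome, chosen prey, reward).
#' @export
simulate_session <- function(config, n_trials, seed = 1,
                             policy = "pursuit") {
  stopifnot(n_trials >= 1)
  cfg <- config
  vars <- c("self", "chosen_prey",
            if (cfg$n_prey >= 2) "unchosen_prey",
            if (cfg$predator_enabled) "predator")
  gap <- cfg$inter_trial_gap_frames
  runs <- lapply(seq_len(n_trials), function(i)
    simulate_trial(cfg, policy = policy, seed = child_seed(seed, "trial", i)))

  lens <- vapply(runs, function(r) nrow(r$trajectories$self), integer(1))
  n_frames <- as.integer(sum(lens) + gap * (n_trials - 1L))
  traj <- lapply(vars, function(v) list(
    x = rep(NA_real_, n_frames), y = rep(NA_real_, n_frames),
    valid = rep(FALSE, n_frames)))
  names(traj) <- vars

  trials <- vector("list", n_trials)
  at <- 0L
  for (i in seq_len(n_trials)) {
    r <- runs[[i]]
    rec <- r$record
    idx <- at + seq_len(lens[i])
    src <- list(self = r$trajectories$self)
    ch <- rec$chosen_prey_id
    src$chosen_prey <- r$trajectories[[paste0("prey", ch)]]
    if (cfg$n_prey >= 2) {
      un <- setdiff(seq_len(cfg$n_prey), ch)[1]
      src$unchosen_prey <- r$trajectories[[paste0("prey", un)]]
    }
    if (cfg$predator_enabled) src$predator <- r$trajectories$predator
    for (v in vars) {
      traj[[v]]$x[idx] <- src[[v]][, 1]
      traj[[v]]$y[idx] <- src[[v]][, 2]
      traj[[v]]$valid[idx] <- TRUE
    }
    trials[[i]] <- data.frame(
      trial_id = i, start_frame = at + 1L, end_frame = at + lens[i],
      outcome = rec$outcome, chosen_prey_id = rec$chosen_prey_id,
      reward = rec$reward, stringsAsFactors = FALSE
    )
    at <- at + lens[i] + if (i < n_trials) gap else 0L
  }
  structure(list(
    config = cfg, frame_dt = cfg$frame_dt, n_frames = n_frames,
    t_s = (seq_len(n_frames) - 1L) * cfg$frame_dt,
    traj = traj, trials = do.call(rbind, trials)
  ), class = "pursuit_session")
}

#' @export
print.pursuit_session <- function(x, ...) {
  cat("<pursuit_session> ", x$n_frames, " frames (",
      round(x$n_frames * x$frame_dt, 1), " s), ",
      nrow(x$trials), " trials (",
      sum(x$trials$outcome == "captured"), " captured), variables: ",
      paste(names(x$traj), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate gaze as Markov target-following
#'
#' Adds a `gaze` trajectory to a session: at each frame the gaze sits on a
#' currently followed target (switching targets as a Poisson process at
#' `switch_rate` per second, with switch destinations drawn by
#' `follow_weights`) plus isotropic Gaussian jitter, clipped to the screen.
#' Frames are invalid with probability `dropout_prob` (modelling frames where
#' gaze could not be estimated) or when the followed target is itself invalid.
#'
#' @param session A [simulate_session()] result.
#' @param follow_weights Named nonnegative weights over session variables.
#' @param switch_rate Target-switch rate, 1/s.
#' @param jitter_sd Isotropic gaze jitter SD, px.
#' @param dropout_prob Per-frame probability of a missing gaze sample.
#' @param seed Integer seed.
#' @return The session with `traj$gaze` added.
#' @export
simulate_gaze <- function(session, follow_weights = c(self = 0.4,
                                                      chosen_prey = 0.6),
                          switch_rate = 1, jitter_sd = 20,
                          dropout_prob = 0.05, seed = 1) {
  stopifnot(all(follow_weights >= 0), sum(follow_weights) > 0,
            all(names(follow_weights) %in% names(session$traj)))
  cfg <- session$config
  n <- session$n_frames
  with_seed(child_seed(seed, "gaze"), {
    targets <- names(follow_weights)
    p <- follow_weights / sum(follow_weights)
    cur <- sample(targets, 1, prob = p)
    switch_p <- min(1, switch_rate * session$frame_dt)
    tgt_idx <- character(n)
    for (f in seq_len(n)) {
      if (stats::runif(1) < switch_p) cur <- sample(targets, 1, prob = p)
      tgt_idx[f] <- cur
    }
    gx <- gy <- rep(NA_real_, n); ok <- rep(FALSE, n)
    jit <- matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
    drop <- stats::runif(n) < dropout_prob
    for (v in targets) {
      sel <- tgt_idx == v & session$traj[[v]]$valid & !drop
      gx[sel] <- pmin(pmax(session$traj[[v]]$x[sel] + jit[sel, 1], 0),
                      cfg$field_width)
      gy[sel] <- pmin(pmax(session$traj[[v]]$y[sel] + jit[sel, 2], 0),
                      cfg$field_height)
      ok[sel] <- TRUE
    }
    session$traj$gaze <- list(x = gx, y = gy, valid = ok)
    session
  })
}
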