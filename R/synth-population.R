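# Ground-truth populations: tuning maps in log-rate space with plantable
# subspace geometry, plus the Poisson spike generator that drives every
# downstream analysis with known truth.

#' Plant a population with controlled subspace geometry
#'
#' Builds `n_neurons` log-rate tuning maps (one `6 x 6` map per variable,
#' stored as `n_neurons x 36` weight matrices) whose population geometry is
#' known exactly:
#'
#' * each variable's maps live in a `d`-dimensional neuron-space subspace
#'   with orthonormal basis `Q_v`; all principal angles between variable `v`
#'   and the first (reference) variable equal `angles_deg[v]`;
#' * latent bin patterns have orthogonal rows of equal norm, so the
#'   population covariance of variable `v` is isotropic on `span(Q_v)` and
#'   the alignment index between two planted variables is `cos^2(theta)`;
#' * if `linear_map` is given, the target variable's latent coordinates are
#'   exactly `W_true` times the source variable's (before noise);
#' * if `axis_relations` is given, each variable also carries a left/right
#'   rank-one component `axis_strength * a_v * sign(x-side)`, with `a_v`
#'   equal to, minus, or orthogonal to the reference axis (relations
#'   `"shared"`, `"inverted"`, `"orthogonal"`), planting the ground truth for
#'   cross-condition decoding.
#'
#' @param n_neurons Number of neurons.
#' @param variables Character vector of variable names; the first is the
#'   geometry reference.
#' @param d Latent dimensionality per variable (`<= 36` and `<= n_neurons`).
#' @param angles_deg Named vector of planted principal angles (degrees, in
#'   `[0, 90]`) between each non-reference variable's subspace and the
#'   reference subspace; unnamed variables default to 90.
#' @param latent_sd Per-bin RMS amplitude of the subspace component of the
#'   log-rate maps.
#' @param map_noise_sd SD of i.i.d. Gaussian noise added to the weight maps.
#' @param linear_map Optional `list(from =, to =, W =)` with `W` a `d x d`
#'   matrix tying the two variables' latent coordinates.
#' @param axis_relations Optional named character vector over non-reference
#'   variables: `"shared"`, `"inverted"` or `"orthogonal"`.
#' @param axis_strength Per-neuron log-rate amplitude of the left/right
#'   component (0 disables it for the reference too).
#' @param baseline_hz Length-2 range; baselines are drawn log-uniformly.
#' @param seed Integer seed.
#' @return A `"planted_population"`: `weights` (named list of
#'   `n_neurons x 36` matrices), `baseline_hz`, `tuned` (per-neuron variable
#'   sets), and `geometry` (bases `Q`, latents `A`, axes, `W_true`, angles).
#' @export
plant_population <- function(n_neurons, variables = c("self", "chosen_prey"),
                             d = 4, angles_deg = NULL,
                             latent_sd = 0.35, map_noise_sd = 0,
                             linear_map = NULL, axis_relations = NULL,
                             axis_strength = 0, baseline_hz = c(2, 10),
                             seed = 1) {
  nv <- length(variables)
  stopifnot(nv >= 1, d >= 1, d <= 36, d <= n_neurons)
  ang <- stats::setNames(rep(90, nv), variables)
  ang[variables[1]] <- 0
  if (!is.null(angles_deg)) {
    stopifnot(all(names(angles_deg) %in% variables),
              all(angles_deg >= 0 & angles_deg <= 90))
    ang[names(angles_deg)] <- angles_deg
  }
  need_axes <- !is.null(axis_relations) || axis_strength > 0
  # columns: d reference + d complement per extra variable + axis vectors
  n_dirs <- d + d * (nv - 1) + if (need_axes) nv else 0
  if (n_dirs > n_neurons)
    stop("specification error: planted directions (", n_dirs,
         ") exceed n_neurons (", n_neurons, ")")

  with_seed(child_seed(seed, "population"), {
    basis <- qr.Q(qr(matrix(stats::rnorm(n_neurons * n_dirs),
                            n_neurons, n_dirs)))
    U_ref <- basis[, seq_len(d), drop = FALSE]
    Q <- vector("list", nv); names(Q) <- variables
    Q[[variables[1]]] <- U_ref
    for (j in seq_len(nv - 1)) {
      v <- variables[j + 1]
      comp <- basis[, d + (j - 1) * d + seq_len(d), drop = FALSE]
      th <- ang[v] * pi / 180
      Q[[v]] <- U_ref * cos(th) + comp * sin(th)
    }

    # Latent bin patterns: d orthonormal zero-mean rows, scaled so each
    # map bin has RMS amplitude latent_sd.
    make_latent <- function() {
      G <- matrix(stats::rnorm(36 * d), 36, d)
      G <- sweep(G, 2, colMeans(G)) # zero-mean columns; QR keeps this
      t(qr.Q(qr(G))) * latent_sd * sqrt(36 / d)
    }
    A <- lapply(variables, function(v) make_latent())
    names(A) <- variables
    W_true <- NULL
    if (!is.null(linear_map)) {
      stopifnot(all(c(linear_map$from, linear_map$to) %in% variables),
                all(dim(linear_map$W) == c(d, d)))
      W_true <- linear_map$W
      A[[linear_map$to]] <- W_true %*% A[[linear_map$from]]
    }

    axes <- NULL
    if (need_axes) {
      rel <- stats::setNames(rep("shared", nv), variables)
      if (!is.null(axis_relations)) rel[names(axis_relations)] <- axis_relations
      stopifnot(all(rel %in% c("shared", "inverted", "orthogonal")))
      axis_cols <- basis[, d * nv + seq_len(nv), drop = FALSE] * sqrt(n_neurons)
      a_ref <- axis_cols[, 1]
      axes <- matrix(0, n_neurons, nv, dimnames = list(NULL, variables))
      next_free <- 2L
      for (j in seq_len(nv)) {
        v <- variables[j]
        axes[, v] <- switch(rel[v],
          shared = a_ref,
          inverted = -a_ref,
          orthogonal = { a <- axis_cols[, next_free]; next_free <- next_free + 1L; a }
        )
      }
      attr(axes, "relations") <- rel
    }
    rc <- bin_coords(spatial_grid())
    side <- ifelse(rc[, "col"] <= 3, -1, 1) # left = -1, right = +1

    weights <- lapply(variables, function(v) {
      Wv <- Q[[v]] %*% A[[v]]
      if (need_axes) Wv <- Wv + axis_strength * outer(axes[, v], side)
      if (map_noise_sd > 0)
        Wv <- Wv + matrix(stats::rnorm(length(Wv), 0, map_noise_sd),
                          nrow(Wv), ncol(Wv))
      dimnames(Wv) <- NULL
      Wv
    })
    names(weights) <- variables
    baseline <- exp(stats::runif(n_neurons, log(baseline_hz[1]),
                                 log(baseline_hz[2])))
    structure(list(
      n_neurons = n_neurons, variables = variables,
      weights = weights, baseline_hz = baseline,
      tuned = rep(list(variables), n_neurons),
      geometry = list(Q = Q, A = A, angles_deg = ang, W_true = W_true,
                      axes = axes, side_sign = side, d = d,
                      latent_sd = latent_sd, axis_strength = axis_strength),
      seed = seed
    ), class = "planted_population")
  })
}

#' Plant neurons with simple single-bump tuning
#'
#' A complement to [plant_population()] for encoding-model recovery: each
#' neuron is tuned to an explicit set of variables (possibly empty), with one
#' Gaussian bump per tuned variable in log-rate space at a random bin center.
#' Untuned neurons are constant-rate Poisson.
#'
#' @param assignments List (one element per neuron) of character vectors of
#'   tuned variable names; `character(0)` plants an untuned neuron.
#' @param variables Variables the population knows about (superset of all
#'   assignments).
#' @param bump_log_height Peak of the log-rate bump (e.g. `log(8)` gives a
#'   peak/baseline rate ratio of 8).
#' @param bump_sd_bins Bump SD in bin units.
#' @param baseline_hz Length-2 log-uniform baseline range.
#' @param seed Integer seed.
#' @return A `"planted_population"` (geometry fields `NULL`).
#' @export
plant_tuned_neurons <- function(assignments,
                                variables = c("self", "chosen_prey",
                                              "unchosen_prey"),
                                bump_log_height = log(8), bump_sd_bins = 1.2,
                                baseline_hz = c(3, 12), seed = 1) {
  stopifnot(all(unlist(assignments) %in% variables))
  n <- length(assignments)
  rc <- bin_coords(spatial_grid())
  with_seed(child_seed(seed, "tuned-neurons"), {
    weights <- lapply(variables, function(v) matrix(0, n, 36))
    names(weights) <- variables
    for (i in seq_len(n)) {
      for (v in assignments[[i]]) {
        ctr <- c(stats::runif(1, 1, 6), stats::runif(1, 1, 6))
        bump <- bump_log_height *
          exp(-((rc[, "row"] - ctr[1])^2 + (rc[, "col"] - ctr[2])^2) /
                (2 * bump_sd_bins^2))
        weights[[v]][i, ] <- bump - mean(bump)
      }
    }
    structure(list(
      n_neurons = n, variables = variables, weights = weights,
      baseline_hz = exp(stats::runif(n, log(baseline_hz[1]),
                                     log(baseline_hz[2]))),
      tuned = assignments, geometry = NULL, seed = seed
    ), class = "planted_population")
  })
}

#' Re-measure planted principal angles
#'
#' Recovers the principal angles (degrees) between two planted variables'
#' neuron-space bases directly from the stored population, for verifying the
#' construction.
#'
#' @param population A [plant_population()] result.
#' @param a,b Variable names.
#' @return Numeric vector of `d` principal angles in degrees.
#' @export
planted_angles <- function(population, a, b) {
  Q <- population$geometry$Q
  stopifnot(!is.null(Q), a %in% names(Q), b %in% names(Q))
  # combine cosine- and sine-based singular values for full-range accuracy
  M <- crossprod(Q[[a]], Q[[b]])
  s_cos <- sort(svd(M)$d, decreasing = TRUE)
  s_sin <- sort(svd(Q[[b]] - Q[[a]] %*% M)$d)
  atan2(pmax(s_sin, 0), pmin(pmax(s_cos, -1), 1)) * 180 / pi
}

#' Simulate Poisson spike counts from a session and planted population
#'
#' For each neuron and frame, the firing rate is
#' `lambda = exp(log(baseline) + sum_v w_v[bin_v(t)])` over the neuron's
#' tuned variables, clipped at `rate_ceiling_hz`; counts are
#' `Poisson(lambda * frame_dt)`. Frames where any tuned variable is invalid
#' (inter-trial gaps, missing gaze) fall back to the baseline rate. Each
#' neuron draws from its own child stream, so adding neurons never perturbs
#' existing spike trains.
#'
#' @param session A [simulate_session()] result.
#' @param population A planted population whose variables all exist in the
#'   session.
#' @param seed Integer seed.
#' @param rate_ceiling_hz Hard ceiling on the instantaneous rate.
#' @param grid Spatial grid used to bin positions (defaults to the session
#'   field).
#' @return Integer matrix `n_frames x n_neurons` with `frame_dt` attribute.
#' @export
simulate_spikes <- function(session, population, seed = 1,
                            rate_ceiling_hz = 200, grid = NULL) {
  used <- unique(unlist(population$tuned))
  missing_v <- setdiff(used, names(session$traj))
  if (length(missing_v))
    stop("session lacks variables: ", paste(missing_v, collapse = ", "))
  if (is.null(grid))
    grid <- spatial_grid(session$config$field_width,
                         session$config$field_height)
  n <- session$n_frames
  counts <- matrix(0L, n, population$n_neurons)
  attr(counts, "frame_dt") <- session$frame_dt
  if (n == 0) return(counts)

  bins <- lapply(session$traj[used], function(tr) {
    b <- grid_bin_index(grid, tr$x, tr$y)
    b[!tr$valid] <- NA_integer_
    b
  })
  dt <- session$frame_dt
  for (i in seq_len(population$n_neurons)) {
    eta <- rep(log(population$baseline_hz[i]), n)
    tv <- population$tuned[[i]]
    if (length(tv)) {
      ok <- Reduce(`&`, lapply(bins[tv], function(b) !is.na(b)))
      for (v in tv)
        eta[ok] <- eta[ok] + population$weights[[v]][i, bins[[v]][ok]]
      eta[!ok] <- log(population$baseline_hz[i])
    }
    lam <- pmin(exp(eta), rate_ceiling_hz)
    counts[, i] <- with_seed(child_seed(seed, "spikes", i),
                             stats::rpois(n, lam * dt))
  }
  counts
}

#' Construct a CCGP design with a planted decoding axis
#'
#' Builds a `"ccgp_design"` directly at the population-vector level (no
#' behavioural simulation): each of `n_chunks` chunks contributes 6 left and
#' 6 right rows equal to a per-neuron baseline plus `strength / 2` times
#' `axis` (sign by side) plus i.i.d. Gaussian noise. Planting `-axis` in a
#' second design yields an inverted decoding axis, an orthogonal vector an
#' orthogonal axis; this pins down the ground truth for transfer-direction
#' and axis-angle recovery independently of task dynamics.
#'
#' @param axis Length-`n_neurons` axis vector (any scale; only direction and
#'   `strength` matter after the internal unit-normalization).
#' @param n_chunks Chunks (12 rows each).
#' @param strength Class separation along the unit axis, in noise-SD units
#'   times `noise_sd`.
#' @param noise_sd Row noise SD.
#' @param baseline Per-neuron mean vector (default 0).
#' @param variable Variable label carried by the design.
#' @param seed Integer seed.
#' @return A `"ccgp_design"` as from [build_ccgp_design()].
#' @export
synthetic_ccgp_design <- function(axis, n_chunks = 20, strength = 2,
                                  noise_sd = 1, baseline = 0,
                                  variable = "synthetic", seed = 1) {
  n <- length(axis)
  u <- axis / sqrt(sum(axis^2))
  base <- rep_len(baseline, n)
  rows <- n_chunks * 12L
  with_seed(child_seed(seed, "synth-design", variable), {
    side <- rep(rep(c(-1, 1), each = 6), n_chunks)
    X <- matrix(base, rows, n, byrow = TRUE) +
      outer(side, u * strength * noise_sd / 2) +
      matrix(stats::rnorm(rows * n, 0, noise_sd), rows, n)
    chunk <- rep(seq_len(n_chunks), each = 12L)
    rank <- rep(rep(1:6, 2), n_chunks)
    lab <- factor(ifelse(side < 0, "left", "right"),
                  levels = c("left", "right"))
    structure(list(
      X = X, labels = lab, chunk = chunk,
      bin = rep(c(1:2, 7:8, 13:14, 5:6, 11:12, 17:18), n_chunks),
      key = paste(chunk, as.character(lab), rank, sep = "/"),
      selected_bins = NULL, variable = variable, n_dropped = 0L
    ), class = "ccgp_design")
  })
}
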