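# Map-level similarity: SPAEF with permutation null and half-split noise
# ceiling, agent-preference indices with a bimodality test, and neuron x
# neuron correlation-matrix structure.

map_values <- function(m) {
  if (inherits(m, "rate_map")) m$values else as.numeric(m)
}

#' SPAEF spatial-efficiency similarity between two maps
#'
#' `SPAEF = 1 - sqrt((A - 1)^2 + (B - 1)^2 + (C - 1)^2)` where `A` is the
#' Pearson correlation between the vectorized maps, `B = cv(b) / cv(a)` is
#' the ratio of coefficients of variation (order-sensitive: second over
#' first argument), and `C` is the histogram-intersection similarity of the
#' z-scored maps (`sum min(h_a, h_b) / sum h_a` over `hist_bins` shared
#' equal-width bins spanning the joint range). 1 means perfect matching; 0
#' orthogonal maps; values below 0 indicate anti-correlation. Maps are
#' compared on the smoothed, unnormalized scale (z-scoring happens only
#' inside `C`), since `B` needs real coefficients of variation.
#'
#' @param map_a,map_b 36-vectors or `"rate_map"` objects; must not be
#'   constant.
#' @param hist_bins Number of histogram bins for `C`.
#' @return List of class `"spaef"`: `A`, `B`, `C`, `spaef`.
#' @export
spaef <- function(map_a, map_b, hist_bins = 10) {
  a <- map_values(map_a); b <- map_values(map_b)
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("SPAEF undefined for a constant map (cv undefined)")
  A <- stats::cor(a, b)
  B <- (stats::sd(b) / mean(b)) / (stats::sd(a) / mean(a))
  za <- (a - mean(a)) / stats::sd(a)
  zb <- (b - mean(b)) / stats::sd(b)
  edges <- seq(min(za, zb), max(za, zb), length.out = hist_bins + 1)
  ha <- tabulate(findInterval(za, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), hist_bins)
  hb <- tabulate(findInterval(zb, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), hist_bins)
  C <- sum(pmin(ha, hb)) / sum(ha)
  structure(list(A = A, B = B, C = C,
                 spaef = 1 - sqrt((A - 1)^2 + (B - 1)^2 + (C - 1)^2)),
            class = "spaef")
}

#' Permutation p-value for SPAEF
#'
#' Shuffles the bin order of the second map (preserving the first map's
#' marginal exactly) and returns the add-one-corrected two-sided tail
#' fraction of `|shuffled SPAEF|` reaching `|observed|`.
#'
#' @param map_a,map_b Maps as in [spaef()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param hist_bins Passed to [spaef()].
#' @return List: `spaef` (observed), `p`, `null` (permutation values).
#' @export
spaef_permutation_p <- function(map_a, map_b, n_perm = 1000, seed = 1,
                                hist_bins = 10) {
  stopifnot(n_perm >= 100)
  a <- map_values(map_a); b <- map_values(map_b)
  obs <- spaef(a, b, hist_bins)$spaef
  null <- with_seed(child_seed(seed, "spaef-perm"), {
    vapply(seq_len(n_perm), function(i)
      spaef(a, b[sample.int(length(b))], hist_bins)$spaef, numeric(1))
  })
  list(spaef = obs, p = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1),
       null = null)
}

# Random disjoint halves of the captured trials of a session.
split_trial_halves <- function(session, trial_ids) {
  k <- length(trial_ids)
  half <- sample(trial_ids, floor(k / 2))
  list(half, setdiff(trial_ids, half))
}

#' Half-split SPAEF noise ceiling
#'
#' Estimates, per neuron, the expected SPAEF between two independent
#' estimates of the *same* variable's map: captured trials are split into
#' random halves `n_splits` times, a map is computed from each half, and the
#' ceiling is the mean SPAEF across splits. This bounds attainable
#' cross-variable similarity given the data's noise level.
#'
#' @param session Session object.
#' @param spikes Spike count matrix.
#' @param variable Variable to map.
#' @param n_splits Number of random half-splits.
#' @param seed Integer seed.
#' @param grid,smoothing_sd Map construction parameters.
#' @return List: `per_neuron` ceilings, `population_mean`, `n_splits_used`.
#' @export
spaef_noise_ceiling <- function(session, spikes, variable, n_splits = 1000,
                                seed = 1, grid = NULL, smoothing_sd = 0.5) {
  cap <- session$trials$trial_id[session$trials$outcome == "captured"]
  if (length(cap) < 4)
    stop("need >= 4 captured trials for half-split ceilings")
  n_neurons <- ncol(spikes)
  dt <- attr(spikes, "frame_dt") %||% session$frame_dt
  acc <- matrix(0, n_splits, n_neurons)
  used <- matrix(FALSE, n_splits, n_neurons)
  with_seed(child_seed(seed, "ceiling", variable), {
    for (s in seq_len(n_splits)) {
      hs <- split_trial_halves(session, cap)
      bins <- lapply(hs, function(ids)
        bin_position(session, variable, grid = grid,
                     trial_filter = function(tr) tr$trial_id %in% ids))
      for (i in seq_len(n_neurons)) {
        m1 <- compute_rate_map(spikes[, i], bins[[1]], dt, smoothing_sd)
        m2 <- compute_rate_map(spikes[, i], bins[[2]], dt, smoothing_sd)
        if (stats::sd(m1$values) > 0 && stats::sd(m2$values) > 0) {
          acc[s, i] <- spaef(m1, m2)$spaef
          used[s, i] <- TRUE
        }
      }
    }
  })
  per <- colSums(acc * used) / pmax(colSums(used), 1)
  per[colSums(used) == 0] <- NA_real_
  list(per_neuron = per, population_mean = mean(per, na.rm = TRUE),
       n_splits_used = colSums(used))
}

#' Agent-preference indices with bimodality test
#'
#' For each neuron, tuning strength for a variable is the 95th minus 5th
#' percentile range of its unnormalized (raw) map; the API is the difference
#' between the two variables' strengths after normalizing each by its
#' population-mean strength:
#' `api_i = S_a(i) / mean(S_a) - S_b(i) / mean(S_b)`.
#' A bimodal API distribution would indicate segregated neuron pools; the
#' Hartigan dip test (uniform bootstrap null) quantifies this.
#'
#' @param pm_a,pm_b `"population_matrix"` objects (raw maps are used) for
#'   the two variables, same neuron set.
#' @param n_boot Bootstrap draws for the dip null.
#' @param seed Integer seed.
#' @return List: `api` (per neuron; `NA` where both ranges are zero),
#'   `dip`, `dip_p`, `n_excluded`.
#' @export
agent_preference_indices <- function(pm_a, pm_b, n_boot = 2000, seed = 1) {
  stopifnot(nrow(pm_a$raw) == nrow(pm_b$raw))
  if (nrow(pm_a$raw) < 10) stop("need >= 10 neurons")
  rng <- function(M) apply(M, 1, function(r)
    diff(stats::quantile(r, c(0.05, 0.95), names = FALSE)))
  Sa <- rng(pm_a$raw); Sb <- rng(pm_b$raw)
  bad <- Sa == 0 & Sb == 0
  api <- Sa / mean(Sa[!bad]) - Sb / mean(Sb[!bad])
  api[bad] <- NA_real_
  dt <- dip_test(api[!bad], n_boot = n_boot, seed = seed)
  list(api = api, dip = dt$statistic, dip_p = dt$p_value,
       n_excluded = sum(bad))
}

#' Neuron-correlation structure across variables
#'
#' Computes each variable's `N x N` Pearson correlation matrix of map rows,
#' a shared neuron ordering from centroid-linkage hierarchical clustering of
#' the reference variable's matrix (Euclidean distance between its rows),
#' and the squared Pearson correlation between the upper-triangle entries of
#' every pair of matrices.
#'
#' @param pms Named list of `"population_matrix"` objects (>= 2 variables,
#'   identical neuron sets).
#' @param reference Variable name used for the leaf order.
#' @return List of class `"corr_structure"`: `C` (named list of correlation
#'   matrices), `leaf_order`, `cross_r2` (matrix of pairwise squared
#'   correlations).
#' @export
correlation_structure <- function(pms, reference = names(pms)[1]) {
  stopifnot(length(pms) >= 2, reference %in% names(pms))
  ids <- lapply(pms, `[[`, "neuron_ids")
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("mismatched neuron sets across variables")
  C <- lapply(pms, function(p) stats::cor(t(p$M)))
  hc <- stats::hclust(stats::dist(C[[reference]]), method = "centroid")
  ut <- upper.tri(C[[1]])
  nv <- length(pms)
  r2 <- matrix(1, nv, nv, dimnames = list(names(pms), names(pms)))
  for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
    r2[i, j] <- r2[j, i] <- stats::cor(C[[i]][ut], C[[j]][ut])^2
  }
  structure(list(C = C, leaf_order = hc$order, cross_r2 = r2,
                 reference = reference), class = "corr_structure")
}
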