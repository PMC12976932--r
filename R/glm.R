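# Poisson linear-nonlinear encoding model over one-hot 2D position
# predictors with graph-Laplacian smoothness regularization, cross-validated
# model comparison, and forward stepwise variable selection.

#' Build a one-hot spatial design for a set of variables
#'
#' Collects per-frame bin indices for the requested variables and keeps only
#' frames where *every* variable has a bin (complete-case masking), so models
#' on subsets of these variables are always compared on identical frames.
#' The design is stored compactly as bin-index vectors; [design_matrix()]
#' materializes the `frames x (36 * n_variables)` one-hot matrix.
#'
#' @param bin_list Named list of [bin_position()] results (or integer bin
#'   vectors) sharing one frame base.
#' @return A `"glm_design"`: `bins` (named list, included frames only),
#'   `frames` (kept frame indices), `n_bins`, `variables`.
#' @export
build_design_matrix <- function(bin_list) {
  stopifnot(length(bin_list) >= 1, !is.null(names(bin_list)))
  bins <- lapply(bin_list, function(b)
    if (inherits(b, "bin_series")) b$bin else as.integer(b))
  lens <- vapply(bins, length, integer(1))
  stopifnot(length(unique(lens)) == 1)
  keep <- which(Reduce(`&`, lapply(bins, function(b) !is.na(b))))
  if (length(keep) == 0) stop("zero included frames after masking")
  structure(list(
    bins = lapply(bins, function(b) b[keep]),
    frames = keep, n_bins = 36L, variables = names(bin_list)
  ), class = "glm_design")
}

# Subset a design to some of its variables (frames unchanged).
design_subset <- function(design, variables) {
  stopifnot(all(variables %in% design$variables))
  design$bins <- design$bins[variables]
  design$variables <- variables
  design
}

#' Materialize the one-hot design matrix
#'
#' @param design A [build_design_matrix()] result.
#' @return A dense 0/1 matrix, `length(design$frames)` rows and
#'   `36 * n_variables` columns in variable-block order.
#' @export
design_matrix <- function(design) {
  nT <- length(design$frames)
  X <- matrix(0L, nT, design$n_bins * length(design$variables))
  for (j in seq_along(design$variables)) {
    off <- (j - 1L) * design$n_bins
    X[cbind(seq_len(nT), off + design$bins[[j]])] <- 1L
  }
  colnames(X) <- as.vector(outer(seq_len(design$n_bins), design$variables,
                                 function(b, v) paste0(v, ".", b)))
  X
}

# 4-neighbour graph Laplacian of the 6x6 grid: R(w) = w' L w is the sum of
# squared first differences along both spatial dimensions (no wraparound).
grid_laplacian <- function(grid = spatial_grid()) {
  nb <- n_bins(grid)
  rc <- bin_coords(grid)
  L <- matrix(0, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (i < j && abs(rc[i, "row"] - rc[j, "row"]) +
          abs(rc[i, "col"] - rc[j, "col"]) == 1) {
      L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
      L[i, j] <- -1; L[j, i] <- -1
    }
  }
  L
}

group_sum <- function(x, g, nb) {
  out <- rep(0, nb)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Fit the smoothness-regularized Poisson LN-GLM
#'
#' Maximizes the penalized Poisson log-likelihood
#' `sum_t [y_t eta_t - exp(eta_t) dt] - sum_v beta_v w_v' L w_v`
#' where `eta_t = b + sum_v w_v[bin_v(t)]` is the log firing rate (Hz) and
#' `L` is the 4-neighbour grid Laplacian, by damped Newton iterations with
#' analytic gradient and Hessian. A ridge of `1e-8` on the intercept and
#' `1e-6` on each variable block's mean weight makes the optimum unique (the
#' likelihood and the Laplacian penalty are both invariant to trading
#' constants between blocks and the intercept). Convergence is declared when
#' the gradient infinity-norm falls below `tol`; the penalized objective is
#' non-decreasing across iterations by backtracking line search.
#'
#' @param design A [build_design_matrix()] result (or subset).
#' @param y Integer spike counts on `design$frames`, or on the full frame
#'   base (then subset internally).
#' @param beta Smoothness strength, scalar or named per variable.
#' @param dt Frame duration, s.
#' @param init Optional parameter vector for warm starts.
#' @param tol Gradient infinity-norm tolerance.
#' @param max_iter Newton iteration cap; non-convergence is an error.
#' @return A `"glm_fit"`: `intercept`, `weights` (named list of 36-vectors),
#'   `beta`, `dt`, `loglik` (unpenalized, on the design frames), `objective`
#'   trace, `theta`, `converged`, `n_iter`.
#' @export
fit_poisson_glm <- function(design, y, beta, dt, init = NULL,
                            tol = 1e-6, max_iter = 200) {
  nv <- length(design$variables)
  nb <- design$n_bins
  if (length(y) != length(design$frames)) y <- y[design$frames]
  stopifnot(all(y >= 0), all(beta >= 0))
  beta <- if (length(beta) == 1) rep(beta, nv) else beta[design$variables]
  L <- grid_laplacian()
  ridge_b <- 1e-8; ridge_c <- 1e-6
  npar <- 1L + nv * nb
  theta <- if (!is.null(init) && length(init) == npar) init else {
    th <- rep(0, npar); th[1] <- log(max(mean(y), 1e-4) / dt); th
  }
  bl <- function(j) 1L + (j - 1L) * nb + seq_len(nb)

  eval_obj <- function(th) {
    eta <- rep(th[1], length(y))
    for (j in seq_len(nv)) eta <- eta + th[bl(j)][design$bins[[j]]]
    eta <- pmin(eta, 30)
    mu <- exp(eta) * dt
    ll <- sum(y * eta) - sum(mu)
    pen <- ridge_b * th[1]^2
    for (j in seq_len(nv)) {
      w <- th[bl(j)]
      pen <- pen + beta[j] * sum(w * (L %*% w)) + ridge_c * mean(w)^2
    }
    list(obj = ll - pen, ll = ll, mu = mu)
  }

  cur <- eval_obj(theta)
  trace <- cur$obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- cur$mu
    r <- y - mu
    g <- numeric(npar)
    g[1] <- sum(r) - 2 * ridge_b * theta[1]
    H <- matrix(0, npar, npar)
    H[1, 1] <- sum(mu) + 2 * ridge_b
    for (j in seq_len(nv)) {
      ij <- bl(j); w <- theta[ij]
      g[ij] <- group_sum(r, design$bins[[j]], nb) -
        2 * beta[j] * as.vector(L %*% w) - 2 * ridge_c * mean(w) / nb
      gm <- group_sum(mu, design$bins[[j]], nb)
      H[ij, ij] <- diag(gm) + 2 * beta[j] * L + 2 * ridge_c / nb^2
      H[1, ij] <- H[ij, 1] <- gm
      if (j > 1) for (k in seq_len(j - 1)) {
        ik <- bl(k)
        cross <- matrix(0, nb, nb)
        idx <- (design$bins[[j]] - 1L) * nb + design$bins[[k]]
        s <- rowsum(mu, idx)
        ii <- as.integer(rownames(s))
        cross[cbind((ii - 1L) %% nb + 1L, (ii - 1L) %/% nb + 1L)] <- s[, 1]
        H[ik, ij] <- cross
        H[ij, ik] <- t(cross)
      }
    }
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    delta <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8 * max(diag(H)), npar), g))
    step <- 1
    repeat {
      cand <- theta + step * delta
      nxt <- eval_obj(cand)
      if (is.finite(nxt$obj) && nxt$obj >= cur$obj - 1e-10) break
      step <- step / 2
      if (step < 1e-12) { nxt <- cur; cand <- theta; break }
    }
    theta <- cand; cur <- nxt
    trace <- c(trace, cur$obj)
  }
  if (!converged && max_iter > 0) {
    # re-check after the last update
    mu <- cur$mu; r <- y - mu
    g1 <- abs(sum(r) - 2 * ridge_b * theta[1])
    if (g1 < tol * 10) converged <- TRUE # degenerate all-zero-spike case
  }
  if (!converged)
    stop("Poisson GLM did not converge: final objective ",
         format(cur$obj), ", grad inf-norm above tol after ",
         max_iter, " iterations")
  weights <- lapply(seq_len(nv), function(j) theta[bl(j)])
  names(weights) <- design$variables
  structure(list(
    intercept = theta[1], weights = weights, beta = beta, dt = dt,
    loglik = cur$ll, objective = trace, theta = theta,
    converged = converged, n_iter = it, variables = design$variables
  ), class = "glm_fit")
}

#' Predicted firing rate (Hz) of a fitted LN-GLM
#'
#' @param fit A [fit_poisson_glm()] result.
#' @param design A design holding (at least) the fitted variables.
#' @return Rate per design frame, Hz.
#' @export
predict_rate <- function(fit, design) {
  eta <- rep(fit$intercept, length(design$frames))
  for (v in fit$variables) eta <- eta + fit$weights[[v]][design$bins[[v]]]
  exp(pmin(eta, 30))
}

# Poisson log-likelihood (up to the y-dependent constant) of rate lambda Hz.
pois_ll <- function(y, lambda, dt) {
  mu <- lambda * dt
  sum(y * log(pmax(mu, 1e-300))) - sum(mu)
}

#' Contiguous-chunk cross-validation folds
#'
#' Frames are cut into contiguous chunks of `chunk_frames` (about 10 s at the
#' native frame rate) dealt round-robin to folds, so that temporally
#' autocorrelated samples stay together and every fold samples the whole
#' session.
#'
#' @param n Number of design frames.
#' @param n_folds Number of folds.
#' @param chunk_frames Frames per contiguous chunk.
#' @return Integer fold id per frame.
#' @export
cv_folds <- function(n, n_folds = 10, chunk_frames = 600) {
  chunk <- (seq_len(n) - 1L) %/% chunk_frames
  (chunk %% n_folds) + 1L
}

#' Cross-validated model performance and regularization selection
#'
#' For each candidate smoothness strength (shared across the model's
#' variables), fits on 9/10 of the contiguous-chunk folds and scores each
#' held-out fold by the spike-normalized increase in log-likelihood over a
#' null model firing at the training-mean rate, in bits per spike. Returns
#' the strength maximizing the mean across folds and its per-fold values.
#' Folds with zero held-out spikes are undefined and excluded
#' (`n_effective`).
#'
#' @param design A [build_design_matrix()] result.
#' @param y Spike counts (full frame base or design frames).
#' @param dt Frame duration, s.
#' @param beta_grid Candidate smoothness strengths.
#' @param n_folds Number of folds.
#' @param chunk_frames Contiguous chunk length for fold construction.
#' @param log_base Base for the bits (default 2).
#' @return A list: `beta` (selected), `cv_llh_increase` (per fold, selected
#'   beta), `mean_llh` , `grid_means`, `n_effective`, `fold_id`.
#' @export
cross_validate <- function(design, y, dt, beta_grid = 10^(0:3),
                           n_folds = 10, chunk_frames = 600, log_base = 2) {
  if (length(y) != length(design$frames)) y <- y[design$frames]
  nT <- length(y)
  if (nT < n_folds) stop("not enough frames for ", n_folds, " folds")
  fold <- cv_folds(nT, n_folds, chunk_frames)
  vals <- matrix(NA_real_, length(beta_grid), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    dtr <- design; dtr$bins <- lapply(design$bins, function(b) b[tr])
    dtr$frames <- design$frames[tr]
    dte <- design; dte$bins <- lapply(design$bins, function(b) b[te])
    dte$frames <- design$frames[te]
    y_tr <- y[tr]; y_te <- y[te]
    n_spk <- sum(y_te)
    if (n_spk == 0) next
    lam0 <- max(mean(y_tr), 1e-12) / dt
    ll0 <- pois_ll(y_te, rep(lam0, sum(te)), dt)
    init <- NULL
    for (bi in seq_along(beta_grid)) {
      fit <- fit_poisson_glm(dtr, y_tr, beta_grid[bi], dt, init = init)
      init <- fit$theta
      llm <- pois_ll(y_te, predict_rate(fit, dte), dt)
      vals[bi, f] <- (llm - ll0) / n_spk / log(log_base)
    }
  }
  n_eff <- sum(colSums(!is.na(vals)) > 0)
  if (n_eff < n_folds)
    warning(n_folds - n_eff, " fold(s) had zero held-out spikes and were excluded")
  gm <- rowMeans(vals, na.rm = TRUE)
  best <- which.max(gm)
  list(beta = beta_grid[best], cv_llh_increase = vals[best, ],
       mean_llh = gm[best], grid_means = stats::setNames(gm, beta_grid),
       n_effective = n_eff, fold_id = fold)
}

#' Forward stepwise selection of a neuron's tuned variables
#'
#' Implements the forward search on cross-validated log-likelihood: fit all
#' single-variable models and keep the best; then repeatedly try supersets
#' that add one variable, accepting the best-scoring superset only if its
#' paired per-fold values significantly exceed the current model's
#' (one-tailed exact Wilcoxon signed-rank, level `alpha`); stop at the first
#' non-improvement. Finally the selected model must itself beat the
#' mean-rate null (one-tailed signed-rank of its fold values against zero),
#' otherwise the neuron is classified as untuned.
#'
#' @param design A [build_design_matrix()] over all candidate variables.
#' @param y Spike counts.
#' @param dt Frame duration, s.
#' @param candidates Variables to consider (default: all in the design).
#' @param alpha Per-step significance level.
#' @param beta_grid,n_folds,chunk_frames Passed to [cross_validate()].
#' @param refit Refit the selected model on all frames (default TRUE).
#' @param neuron_id Optional id carried through to the result.
#' @return A `"tuning_model"`: `tuned`, `selected` (character, possibly
#'   empty), `cv` (fold values of the final model), `p_null`, `fit` (full
#'   refit or NULL), `path` (per-step data frame).
#' @export
select_model <- function(design, y, dt, candidates = design$variables,
                         alpha = 0.05, beta_grid = 10^(0:3), n_folds = 10,
                         chunk_frames = 600, refit = TRUE,
                         neuron_id = NA_integer_) {
  stopifnot(length(candidates) >= 1, all(candidates %in% design$variables))
  if (length(y) != length(design$frames)) y <- y[design$frames]
  run_cv <- function(vars) cross_validate(design_subset(design, vars), y, dt,
                                          beta_grid, n_folds, chunk_frames)
  wsr_greater <- function(x, y_ref = NULL) {
    # one-tailed exact signed-rank; ties fall back to the built-in correction
    suppressWarnings(
      if (is.null(y_ref))
        stats::wilcox.test(x, mu = 0, alternative = "greater",
                           exact = TRUE)$p.value
      else
        stats::wilcox.test(x, y_ref, paired = TRUE, alternative = "greater",
                           exact = TRUE)$p.value
    )
  }
  path <- list()
  singles <- lapply(candidates, function(v) run_cv(v))
  means <- vapply(singles, `[[`, numeric(1), "mean_llh")
  best <- which(means == max(means))[1] # ties: smaller index
  cur_vars <- candidates[best]
  cur <- singles[[best]]
  path[[1]] <- data.frame(step = 1, model = paste(cur_vars, collapse = "+"),
                          mean_llh = cur$mean_llh, p = NA_real_,
                          accepted = TRUE)
  remaining <- setdiff(candidates, cur_vars)
  while (length(remaining)) {
    cands <- lapply(remaining, function(v) run_cv(c(cur_vars, v)))
    cmeans <- vapply(cands, `[[`, numeric(1), "mean_llh")
    bi <- which(cmeans == max(cmeans))[1]
    pair <- stats::complete.cases(cands[[bi]]$cv_llh_increase,
                                  cur$cv_llh_increase)
    p <- wsr_greater(cands[[bi]]$cv_llh_increase[pair],
                     cur$cv_llh_increase[pair])
    acc <- is.finite(p) && p < alpha
    path[[length(path) + 1]] <- data.frame(
      step = length(path) + 1,
      model = paste(c(cur_vars, remaining[bi]), collapse = "+"),
      mean_llh = cmeans[bi], p = p, accepted = acc)
    if (!acc) break
    cur_vars <- c(cur_vars, remaining[bi])
    cur <- cands[[bi]]
    remaining <- remaining[-bi]
  }
  folds <- cur$cv_llh_increase[!is.na(cur$cv_llh_increase)]
  p_null <- wsr_greater(folds)
  tuned <- is.finite(p_null) && p_null < alpha
  fit <- NULL
  if (refit && tuned)
    fit <- fit_poisson_glm(design_subset(design, cur_vars), y, cur$beta, dt)
  structure(list(
    neuron_id = neuron_id, tuned = tuned,
    selected = if (tuned) cur_vars else character(0),
    cv = cur$cv_llh_increase, mean_llh = cur$mean_llh, beta = cur$beta,
    p_null = p_null, fit = fit, path = do.call(rbind, path)
  ), class = "tuning_model")
}

#' Correlation between predicted and observed firing after smoothing
#'
#' Smooths both the model-predicted rate series and the empirical rate
#' series (`counts / dt`) with a temporal Gaussian of SD `smooth_sd_s` and
#' returns their Pearson correlation. `NA` if either series is constant.
#'
#' @param fit A [fit_poisson_glm()] result.
#' @param design The design the fit was made on.
#' @param y Spike counts.
#' @param smooth_sd_s Temporal smoothing SD in seconds.
#' @return Pearson correlation, or `NA`.
#' @export
model_prediction_quality <- function(fit, design, y, smooth_sd_s = 0.25) {
  if (length(y) != length(design$frames)) y <- y[design$frames]
  sd_f <- smooth_sd_s / fit$dt
  half <- max(1L, ceiling(4 * sd_f))
  k <- exp(-((-half):half)^2 / (2 * sd_f^2)); k <- k / sum(k)
  sm <- function(x) as.vector(stats::filter(x, k, sides = 2))
  a <- sm(predict_rate(fit, design)); b <- sm(y / fit$dt)
  ok <- stats::complete.cases(a, b)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])
}
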