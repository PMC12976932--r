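# Population-subspace geometry: cross-variable PCA variance, alignment index
# with a covariance-matched random-subspace null, half-split covariance
# correlation, joint mutually-orthogonal subspace optimization on the
# Stiefel manifold, and linear maps between subspace coordinates.
#
# Covariance conventions: neuron-space covariance C = M %*% t(M) / (nbin - 1)
# (N x N, M the neurons x 36 matrix) for all alignment / PCA / subspace
# operations; condition-space covariance t(M) %*% M / (N - 1) (36 x 36) for
# the half-split covariance correlation. Each matches the dimensional
# requirement of its formula.

neuron_cov <- function(M) tcrossprod(M) / (ncol(M) - 1)
condition_cov <- function(M) crossprod(M) / (nrow(M) - 1)

top_eig <- function(C, k) {
  e <- eigen(C, symmetric = TRUE)
  list(vectors = e$vectors[, seq_len(k), drop = FALSE],
       values = e$values[seq_len(k)], all_values = e$values)
}

#' Variance of other variables captured by a reference variable's PCs
#'
#' Applies PCA to the reference population matrix (neuron-space directions
#' from the transposed `36 x N` matrix) and reports, for each other
#' variable, the fraction of its total variance that falls inside the top-k
#' reference-PC subspace.
#'
#' @param m_ref Reference `"population_matrix"` (or plain `N x 36` matrix).
#' @param others Named list of other matrices on the same neuron set.
#' @param k Number of reference PCs.
#' @return List: `var_explained_ref` (top-k fraction of the reference's own
#'   variance), `var_explained_other` (named fractions), `pcs` (`N x k`).
#' @export
pca_cross_variance <- function(m_ref, others, k = 10) {
  M <- pm_matrix(m_ref, drop_flat = FALSE)
  if (nrow(M) <= k) stop("need more than k = ", k, " neurons")
  C <- neuron_cov(M)
  e <- top_eig(C, k)
  fr <- function(Mo) {
    Co <- neuron_cov(pm_matrix(Mo, drop_flat = FALSE))
    sum(diag(crossprod(e$vectors, Co %*% e$vectors))) / sum(diag(Co))
  }
  list(
    var_explained_ref = sum(e$values) / sum(e$all_values),
    var_explained_other = vapply(others, fr, numeric(1)),
    pcs = e$vectors
  )
}

#' Alignment index between two population matrices
#'
#' `AI = tr(D_a' C_b D_a) / sum_{i<=k} sigma_b(i)`, where `D_a` holds the
#' top-k principal components of variable `a` (neuron space) and
#' `sigma_b(i)` are the top-k eigenvalues of variable `b`'s covariance: the
#' fraction of `b`'s best-case k-dimensional variance that lies inside `a`'s
#' top-k subspace. 0 = orthogonal subspaces, 1 = collinear. The null draws
#' `n_null` random k-dimensional bases from the covariance of the
#' variable-concatenated data (`v_j = C_comb^{1/2} u_j`, orthonormalized)
#' and the one-sided p-value is the add-one-corrected fraction of null AIs
#' *smaller* than the observed (small p = more orthogonal than chance).
#'
#' @param m_a,m_b `"population_matrix"` objects or `N x 36` matrices, same
#'   neuron set.
#' @param k Subspace dimensionality.
#' @param n_null Random-basis draws (0 skips the null).
#' @param seed Integer seed.
#' @return List of class `"alignment_result"`: `ai`, `k`, `null`, `p`.
#' @export
alignment_index <- function(m_a, m_b, k = 10, n_null = 1000, seed = 1) {
  Ma <- pm_matrix(m_a, drop_flat = FALSE)
  Mb <- pm_matrix(m_b, drop_flat = FALSE)
  stopifnot(nrow(Ma) == nrow(Mb))
  if (nrow(Ma) <= k) stop("need N > k")
  Ca <- neuron_cov(Ma); Cb <- neuron_cov(Mb)
  eb <- top_eig(Cb, k)
  Da <- top_eig(Ca, k)$vectors
  ai_of <- function(D) sum(diag(crossprod(D, Cb %*% D))) / sum(eb$values)
  ai <- ai_of(Da)
  null <- NULL; p <- NA_real_
  if (n_null > 0) {
    Cc <- neuron_cov(cbind(Ma, Mb))
    ec <- eigen(Cc, symmetric = TRUE)
    if (sum(ec$values > max(ec$values) * 1e-12) < k)
      stop("combined covariance has rank below k")
    half <- ec$vectors %*% (sqrt(pmax(ec$values, 0)) * t(ec$vectors))
    null <- with_seed(child_seed(seed, "ai-null"), {
      vapply(seq_len(n_null), function(i) {
        V <- half %*% matrix(stats::rnorm(nrow(Ca) * k), ncol = k)
        ai_of(qr.Q(qr(V)))
      }, numeric(1))
    })
    p <- (1 + sum(null < ai)) / (n_null + 1)
  }
  structure(list(ai = ai, k = k, null = null, p = p),
            class = "alignment_result")
}

#' Half-split covariance correlation between two variables
#'
#' Per iteration, captured trials are split into two random halves and maps
#' are recomputed per half. The within floor correlates the two halves'
#' condition-space covariance matrices for variable `a` (upper-triangle
#' off-diagonal entries); the cross value correlates variable `a`'s matrix
#' from the first half with variable `b`'s from the second half of the
#' *identical* split, so that within and cross rest on the same amount of
#' data with independent noise (pairing a variable with itself makes the two
#' quantities exact ties). The one-sided p-value is the fraction of
#' iterations where the cross correlation reaches the within correlation
#' (random tie-break): small p means the cross-variable similarity sits
#' significantly below the within-variable noise ceiling.
#'
#' @param session,spikes Session and spike matrix.
#' @param var_a,var_b Variable names.
#' @param n_iter Number of random splits.
#' @param seed Integer seed.
#' @param grid,smoothing_sd Map construction parameters.
#' @return List: `r2_cross`, `r2_within_floor` (mean squared correlations),
#'   `r_cross`, `r_within`, `p`.
#' @export
covariance_split_correlation <- function(session, spikes, var_a, var_b,
                                         n_iter = 500, seed = 1,
                                         grid = NULL, smoothing_sd = 0.5) {
  cap <- session$trials$trial_id[session$trials$outcome == "captured"]
  if (length(cap) < 4) stop("need >= 4 captured trials")
  dt <- attr(spikes, "frame_dt") %||% session$frame_dt
  covs_from <- function(v, ids) {
    b <- bin_position(session, v, grid = grid,
                      trial_filter = function(tr) tr$trial_id %in% ids)
    pm <- build_population_matrix(rate_maps(spikes, b,
                                            smoothing_sd = smoothing_sd))
    condition_cov(pm_matrix(pm, drop_flat = FALSE))
  }
  ut <- upper.tri(matrix(0, 36, 36))
  r_w <- r_c <- numeric(n_iter)
  wins <- numeric(n_iter)
  with_seed(child_seed(seed, "cov-split", var_a, var_b), {
    for (s in seq_len(n_iter)) {
      hs <- split_trial_halves(session, cap)
      Ca1 <- covs_from(var_a, hs[[1]]); Ca2 <- covs_from(var_a, hs[[2]])
      Cb2 <- covs_from(var_b, hs[[2]])
      r_w[s] <- stats::cor(Ca1[ut], Ca2[ut])
      r_c[s] <- stats::cor(Ca1[ut], Cb2[ut])
      wins[s] <- if (r_w[s] == r_c[s]) stats::rbinom(1, 1, 0.5)
                 else as.numeric(r_c[s] >= r_w[s])
    }
  })
  list(r2_cross = mean(r_c^2), r2_within_floor = mean(r_w^2),
       r_cross = mean(r_c), r_within = mean(r_w), p = mean(wins))
}

# --- Stiefel-manifold optimization --------------------------------------

# Objective: mean over variables of tr(Q_v' C_v Q_v) / (top-d_v eigenvalue
# sum of C_v), over the joint Stiefel manifold Q = [Q_1 ... Q_V].
stiefel_objective <- function(Q, C_list, d_list, denom) {
  off <- 0; val <- 0
  for (v in seq_along(C_list)) {
    Qv <- Q[, off + seq_len(d_list[v]), drop = FALSE]
    val <- val + sum(diag(crossprod(Qv, C_list[[v]] %*% Qv))) / denom[v]
    off <- off + d_list[v]
  }
  val / length(C_list)
}

stiefel_egrad <- function(Q, C_list, d_list, denom) {
  G <- matrix(0, nrow(Q), ncol(Q))
  off <- 0
  for (v in seq_along(C_list)) {
    j <- off + seq_len(d_list[v])
    G[, j] <- 2 * (C_list[[v]] %*% Q[, j, drop = FALSE]) / denom[v]
    off <- off + d_list[v]
  }
  G / length(C_list)
}

qr_retract <- function(Y) {
  qrd <- qr(Y)
  Qn <- qr.Q(qrd)
  s <- sign(diag(qr.R(qrd))); s[s == 0] <- 1
  sweep(Qn, 2, s, "*")
}

#' Jointly optimal mutually orthogonal subspaces
#'
#' Finds per-variable orthonormal bases `Q_v` (`N x d_v`), mutually
#' orthogonal across variables, maximizing the mean normalized captured
#' variance `(1/V) sum_v tr(Q_v' C_v Q_v) / sum_{i<=d_v} sigma_v(i)` by
#' Riemannian gradient ascent on the Stiefel manifold of the joined matrix
#' `[Q_1 ... Q_V]` with QR retraction, backtracking line search (monotone
#' objective), and multi-start.
#'
#' @param C_list Named list of symmetric PSD neuron-space covariances.
#' @param d_list Subspace dimensionalities (recycled; default 4 each).
#' @param n_starts Random restarts (best kept).
#' @param max_iter Iteration cap per start.
#' @param tol_obj,tol_grad Convergence: relative objective change below
#'   `tol_obj` or gradient norm below `tol_grad`.
#' @param seed Integer seed.
#' @return A `"subspace_basis"`: `Q` (named list of bases), `d`,
#'   `var_captured` (per variable, fraction of its best d_v-dimensional
#'   variance), `objective`, `trace`, `converged`.
#' @export
optimize_orthogonal_subspaces <- function(C_list, d_list = 4, n_starts = 5,
                                          max_iter = 3000, tol_obj = 1e-9,
                                          tol_grad = 1e-6, seed = 1) {
  V <- length(C_list)
  d_list <- rep_len(d_list, V)
  N <- nrow(C_list[[1]])
  stopifnot(sum(d_list) <= N,
            all(vapply(C_list, function(C)
              isTRUE(all.equal(C, t(C), tolerance = 1e-8)), logical(1))))
  denom <- vapply(seq_len(V), function(v) {
    ev <- eigen(C_list[[v]], symmetric = TRUE, only.values = TRUE)$values
    sum(ev[seq_len(d_list[v])])
  }, numeric(1))
  dtot <- sum(d_list)

  run_start <- function(s) {
    Q <- with_seed(child_seed(seed, "stiefel", s),
                   qr_retract(matrix(stats::rnorm(N * dtot), N, dtot)))
    obj <- stiefel_objective(Q, C_list, d_list, denom)
    trace <- obj
    conv <- FALSE
    step <- 1
    stall <- 0L
    for (it in seq_len(max_iter)) {
      G <- stiefel_egrad(Q, C_list, d_list, denom)
      QtG <- crossprod(Q, G)
      rg <- G - Q %*% ((QtG + t(QtG)) / 2) # project to tangent space
      gn <- sqrt(sum(rg^2))
      if (gn < tol_grad) { conv <- TRUE; break }
      # adaptive step: grow after clean steps, backtrack on failure
      step <- min(step * 2, 1e4)
      repeat {
        Qn <- qr_retract(Q + step * rg)
        on <- stiefel_objective(Qn, C_list, d_list, denom)
        if (on >= obj - 1e-14) break
        step <- step / 2
        if (step < 1e-14) { Qn <- Q; on <- obj; break }
      }
      Q <- Qn; obj <- on
      trace <- c(trace, obj)
      # plateau over a window: covers objectives with flat optimum
      # manifolds (e.g. collinear variables) where the gradient never
      # vanishes numerically but progress has stopped
      n_tr <- length(trace)
      if (n_tr > 20 &&
          trace[n_tr] - trace[n_tr - 20] <= tol_obj * 20 * max(1, abs(obj))) {
        conv <- TRUE; break
      }
    }
    list(Q = Q, obj = obj, trace = trace, conv = conv)
  }
  runs <- lapply(seq_len(n_starts), run_start)
  if (!any(vapply(runs, `[[`, logical(1), "conv")))
    stop("Stiefel optimization failed to converge on all ", n_starts,
         " starts; final objectives: ",
         paste(signif(vapply(runs, `[[`, numeric(1), "obj"), 4),
               collapse = ", "))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "obj"))]]
  off <- 0
  Qs <- vector("list", V); names(Qs) <- names(C_list)
  vc <- numeric(V)
  for (v in seq_len(V)) {
    Qs[[v]] <- best$Q[, off + seq_len(d_list[v]), drop = FALSE]
    vc[v] <- sum(diag(crossprod(Qs[[v]], C_list[[v]] %*% Qs[[v]]))) / denom[v]
    off <- off + d_list[v]
  }
  names(vc) <- names(C_list)
  structure(list(Q = Qs, d = d_list, var_captured = vc,
                 objective = best$obj, trace = best$trace,
                 converged = best$conv),
            class = "subspace_basis")
}

#' Variance of each variable captured by each fitted subspace
#'
#' Projects variable `v`'s covariance onto variable `u`'s subspace basis and
#' reports `tr(Q_u' C_v Q_u) / sum_{i<=d_u} sigma_v(i)`: own-subspace
#' entries reproduce the basis' `var_captured`; small off-diagonal entries
#' mean the subspaces separate the variables. Significance is assessed by
#' resampling neurons with replacement (the bases are fixed; projections are
#' recomputed) and reporting, for each cross pair, the fraction of bootstrap
#' cross-capture fractions that reach the own-subspace capture.
#'
#' @param M_list Named list of `N x 36` matrices / population matrices, same
#'   neuron set and order as used to fit `basis`.
#' @param basis A [optimize_orthogonal_subspaces()] result.
#' @param n_boot Bootstrap draws (0 skips).
#' @param seed Integer seed.
#' @return List: `fractions` (variables x subspaces matrix), `p` (same
#'   shape; `NA` on the diagonal).
#' @export
cross_projection_variance <- function(M_list, basis, n_boot = 1000,
                                      seed = 1) {
  Ms <- lapply(M_list, pm_matrix, drop_flat = FALSE)
  V <- length(Ms)
  vars <- names(M_list)
  frac_fun <- function(Ms_in) {
    out <- matrix(NA_real_, V, V, dimnames = list(variable = vars,
                                                  subspace = vars))
    for (v in seq_len(V)) {
      Cv <- neuron_cov(Ms_in[[v]])
      ev <- eigen(Cv, symmetric = TRUE, only.values = TRUE)$values
      for (u in seq_len(V)) {
        Qu <- basis$Q[[vars[u]]]
        out[v, u] <- sum(diag(crossprod(Qu, Cv %*% Qu))) /
          sum(ev[seq_len(ncol(Qu))])
      }
    }
    out
  }
  fr <- frac_fun(Ms)
  p <- matrix(NA_real_, V, V, dimnames = dimnames(fr))
  if (n_boot > 0) {
    N <- nrow(Ms[[1]])
    exceed <- matrix(0, V, V)
    with_seed(child_seed(seed, "crossproj"), {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(N, N, replace = TRUE)
        fb <- frac_fun(lapply(Ms, function(M) M[idx, , drop = FALSE]))
        exceed <- exceed + (fb >= diag(fr)[row(fb)])
      }
    })
    p <- (1 + exceed) / (n_boot + 1)
    diag(p) <- NA_real_
  }
  list(fractions = fr, p = p)
}

#' Project population matrices onto fitted subspaces
#'
#' @param M_list Named list of `N x 36` matrices.
#' @param basis A `"subspace_basis"`.
#' @return Named list of `d_v x 36` latent coordinate matrices
#'   `X_v = Q_v' M_v`.
#' @export
subspace_coordinates <- function(M_list, basis) {
  out <- lapply(names(basis$Q), function(v)
    crossprod(basis$Q[[v]], pm_matrix(M_list[[v]], drop_flat = FALSE)))
  names(out) <- names(basis$Q)
  out
}

#' Linear map between two subspaces' condition coordinates
#'
#' Fits `X_b = W X_a` by ordinary least squares over the 36 spatial-bin
#' conditions (no intercept), with `R^2 = 1 - |X_b - W X_a|_F^2 / |X_b|_F^2`
#' on the full data and under leave-one-bin-out cross-validation. The null
#' permutes the entries within each row of `X_a` independently and refits;
#' `p` is the add-one-corrected fraction of shuffled LOOCV `R^2` values
#' reaching the observed one.
#'
#' @param x_a,x_b `d_a x 36` and `d_b x 36` coordinate matrices.
#' @param n_shuffle Number of shuffles (0 skips).
#' @param seed Integer seed.
#' @return A `"linear_map_result"`: `W`, `r2_train`, `r2_loocv`, `null`,
#'   `p`, `rank_deficient`.
#' @export
fit_linear_map <- function(x_a, x_b, n_shuffle = 1000, seed = 1) {
  Xa <- as.matrix(x_a); Xb <- as.matrix(x_b)
  stopifnot(ncol(Xa) == ncol(Xb))
  nC <- ncol(Xa)
  ols <- function(A, B) {
    # W = argmin |B - W A|_F, minimum-norm under rank deficiency
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    W <- B %*% sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    list(W = W, deficient = sum(pos) < nrow(A))
  }
  r2_of <- function(W, A, B) 1 - sum((B - W %*% A)^2) / sum(B^2)
  loocv_loop <- function(A, B) {
    press <- 0
    for (c_ in seq_len(nC)) {
      Wc <- ols(A[, -c_, drop = FALSE], B[, -c_, drop = FALSE])$W
      press <- press + sum((B[, c_] - Wc %*% A[, c_, drop = FALSE])^2)
    }
    1 - press / sum(B^2)
  }
  loocv_r2 <- function(A, B) {
    # exact leave-one-condition-out via leverages: loo residual of column c
    # is resid_c / (1 - h_c), h_c = a_c' (A A')^{-1} a_c
    G <- tcrossprod(A)
    P <- tryCatch(solve(G), error = function(e) NULL)
    if (is.null(P)) return(loocv_loop(A, B))
    h <- colSums(A * (P %*% A))
    if (any(h > 1 - 1e-10)) return(loocv_loop(A, B))
    W <- B %*% t(A) %*% P
    resid <- sweep(B - W %*% A, 2, 1 - h, "/")
    1 - sum(resid^2) / sum(B^2)
  }
  f <- ols(Xa, Xb)
  obs_cv <- loocv_r2(Xa, Xb)
  null <- NULL; p <- NA_real_
  if (n_shuffle > 0) {
    null <- with_seed(child_seed(seed, "linmap-shuffle"), {
      vapply(seq_len(n_shuffle), function(s) {
        Ap <- t(apply(Xa, 1, sample))
        loocv_r2(Ap, Xb)
      }, numeric(1))
    })
    p <- (1 + sum(null >= obs_cv)) / (n_shuffle + 1)
  }
  structure(list(W = f$W, r2_train = r2_of(f$W, Xa, Xb), r2_loocv = obs_cv,
                 null = null, p = p, rank_deficient = f$deficient),
            class = "linear_map_result")
}
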