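# Cross-condition generalization performance: chunked population designs,
# left/right maximum-margin classification with transfer across variables,
# label-shuffle nulls, decoding-axis angles and their MDS embedding.

#' Chunk a session into fixed-duration rate tables
#'
#' Concatenates the frames of trials passing `trial_filter` (default:
#' captured trials) in session order, cuts them into non-overlapping chunks
#' of `chunk_s` seconds (the trailing remainder is discarded and logged),
#' and computes, per chunk and variable, each neuron's mean firing rate in
#' every spatial bin.
#'
#' @param session,spikes Session object and `frames x neurons` counts.
#' @param chunk_s Chunk duration, seconds.
#' @param variables Variables to tabulate.
#' @param grid Spatial grid (defaults to the session field).
#' @param trial_filter Trial selection, as in [bin_position()].
#' @return A `"ccgp_chunks"`: `rate` (per variable, `neurons x 36 x chunks`
#'   array), `occupancy` (per variable, `36 x chunks`), `session_occupancy`
#'   (per variable, length 36), `n_chunks`, `frames_per_chunk`,
#'   `discarded_frames`.
#' @export
chunk_session <- function(session, spikes, chunk_s = 40,
                          variables = names(session$traj), grid = NULL,
                          trial_filter = function(tr)
                            tr$outcome == "captured") {
  dt <- attr(spikes, "frame_dt") %||% session$frame_dt
  bins <- lapply(variables, function(v)
    bin_position(session, v, grid = grid, trial_filter = trial_filter))
  names(bins) <- variables
  tt <- session$trials
  sel <- if (is.null(trial_filter)) rep(TRUE, nrow(tt)) else trial_filter(tt)
  frames <- unlist(lapply(which(sel), function(i)
    tt$start_frame[i]:tt$end_frame[i]))
  per <- as.integer(round(chunk_s / dt))
  n_chunks <- length(frames) %/% per
  if (n_chunks < 2) stop("concatenated data shorter than 2 chunks")
  used <- frames[seq_len(n_chunks * per)]
  chunk_id <- rep(seq_len(n_chunks), each = per)
  nn <- ncol(spikes)
  rate <- occ <- socc <- vector("list", length(variables))
  names(rate) <- names(occ) <- names(socc) <- variables
  for (v in variables) {
    b <- bins[[v]]$bin[used]
    ok <- !is.na(b)
    cell <- (chunk_id[ok] - 1L) * 36L + b[ok] # (chunk, bin) cell id
    o <- tabulate(cell, nbins = 36L * n_chunks)
    occ[[v]] <- matrix(o, 36, n_chunks)
    socc[[v]] <- rowSums(occ[[v]])
    spk <- rowsum(spikes[used[ok], , drop = FALSE], group = cell)
    num <- matrix(0, 36L * n_chunks, nn)
    num[as.integer(rownames(spk)), ] <- spk
    r <- num / (pmax(o, 1) * dt)
    arr <- array(0, c(nn, 36, n_chunks))
    for (ch in seq_len(n_chunks))
      arr[, , ch] <- t(r[(ch - 1L) * 36L + seq_len(36L), , drop = FALSE])
    rate[[v]] <- arr
  }
  structure(list(rate = rate, occupancy = occ, session_occupancy = socc,
                 n_chunks = n_chunks, frames_per_chunk = per,
                 discarded_frames = length(frames) - n_chunks * per,
                 variables = variables, n_neurons = nn),
            class = "ccgp_chunks")
}

#' Build the left/right CCGP design for one variable
#'
#' The candidate bins are the 12 most leftward (grid columns 1-2) and 12
#' most rightward (columns 5-6) bins; per side, the 6 bins with the highest
#' whole-session occupancy are selected (`bin_rule = "occupancy"`, ties
#' broken by ascending bin index) or 6 random bins (`bin_rule = "random"`).
#' Each selected bin in each chunk contributes one population firing-rate
#' vector; rows whose (chunk, bin) cell has zero occupancy are dropped and
#' counted.
#'
#' @param chunks A [chunk_session()] result.
#' @param variable Variable name.
#' @param n_bins_side Bins kept per side.
#' @param bin_rule `"occupancy"` or `"random"`.
#' @param seed Seed for `bin_rule = "random"`.
#' @return A `"ccgp_design"`: `X` (`rows x neurons`), `labels`
#'   (`"left"`/`"right"` factor), `chunk`, `bin`, `key` (chunk/side/rank row
#'   keys for split pairing across variables), `selected_bins`,
#'   `n_dropped`.
#' @export
build_ccgp_design <- function(chunks, variable, n_bins_side = 6,
                              bin_rule = c("occupancy", "random"),
                              seed = 1) {
  bin_rule <- match.arg(bin_rule)
  stopifnot(variable %in% chunks$variables)
  rc <- bin_coords(spatial_grid())
  sides <- list(left = which(rc[, "col"] <= 2), right = which(rc[, "col"] >= 5))
  socc <- chunks$session_occupancy[[variable]]
  pick <- lapply(names(sides), function(s) {
    cand <- sides[[s]]
    if (bin_rule == "occupancy") {
      cand[order(-socc[cand], cand)][seq_len(n_bins_side)]
    } else {
      with_seed(child_seed(seed, "bin-rule", variable, s),
                sort(sample(cand, n_bins_side)))
    }
  })
  names(pick) <- names(sides)
  rows <- list(); labs <- chs <- bns <- keys <- list()
  drop_n <- 0L
  for (s in names(pick)) {
    bsel <- sort(pick[[s]])
    for (r in seq_along(bsel)) {
      b <- bsel[r]
      for (ch in seq_len(chunks$n_chunks)) {
        if (chunks$occupancy[[variable]][b, ch] == 0) {
          drop_n <- drop_n + 1L; next
        }
        rows[[length(rows) + 1]] <- chunks$rate[[variable]][, b, ch]
        labs[[length(labs) + 1]] <- s
        chs[[length(chs) + 1]] <- ch
        bns[[length(bns) + 1]] <- b
        keys[[length(keys) + 1]] <- paste(ch, s, r, sep = "/")
      }
    }
  }
  if (!length(rows)) stop("empty CCGP design for ", variable)
  structure(list(
    X = do.call(rbind, rows),
    labels = factor(unlist(labs), levels = c("left", "right")),
    chunk = unlist(chs), bin = unlist(bns), key = unlist(keys),
    selected_bins = pick, variable = variable, n_dropped = drop_n
  ), class = "ccgp_design")
}

# Fit a linear maximum-margin classifier and return weights + predict fun.
fit_linear_svm <- function(X, labels, cost = 1) {
  m <- e1071::svm(X, labels, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.vector(t(m$coefs) %*% m$SV)
  if (sum(abs(w)) == 0) stop("degenerate (zero) SVM weight vector")
  list(model = m, w = w)
}

#' Cross-condition generalization performance
#'
#' On each repetition the training design is split 70/30 with class balance;
#' a linear maximum-margin classifier is trained on the z-scored training
#' rows (per-neuron statistics from those rows only) and applied, without
#' retraining and with the same normalization, to the test-context rows
#' whose (chunk, side, rank) keys match the held-out 30%. CCGP is the mean
#' accuracy across repetitions. Training on a context and testing on itself
#' reduces to ordinary held-out decoding.
#'
#' @param train,test `"ccgp_design"` objects on the same neuron set.
#' @param n_reps Number of random splits.
#' @param train_frac Training fraction.
#' @param seed Integer seed.
#' @param cost Margin penalty of the classifier.
#' @return A `"ccgp_result"`: `ccgp` (mean accuracy), `per_rep`,
#'   `train_variable`, `test_variable`.
#' @export
ccgp <- function(train, test, n_reps = 50, train_frac = 0.7, seed = 1,
                 cost = 1) {
  stopifnot(ncol(train$X) == ncol(test$X))
  acc <- with_seed(child_seed(seed, "ccgp", train$variable, test$variable), {
    vapply(seq_len(n_reps), function(rep) {
      for (try in 1:20) {
        tr_idx <- unlist(lapply(levels(train$labels), function(l) {
          rows <- which(train$labels == l)
          sample(rows, round(train_frac * length(rows)))
        }))
        held_keys <- train$key[-tr_idx]
        te_idx <- which(test$key %in% held_keys)
        ok <- length(unique(train$labels[tr_idx])) == 2 &&
          length(te_idx) > 0 &&
          length(unique(train$labels[-tr_idx])) == 2
        if (ok) break
      }
      if (!ok) stop("could not build a class-balanced split in 20 tries")
      mu <- colMeans(train$X[tr_idx, , drop = FALSE])
      sdv <- apply(train$X[tr_idx, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      zs <- function(M) sweep(sweep(M, 2, mu), 2, sdv, "/")
      f <- fit_linear_svm(zs(train$X[tr_idx, , drop = FALSE]),
                          train$labels[tr_idx], cost)
      pred <- stats::predict(f$model, zs(test$X[te_idx, , drop = FALSE]))
      mean(pred == test$labels[te_idx])
    }, numeric(1))
  })
  structure(list(ccgp = mean(acc), per_rep = acc,
                 train_variable = train$variable,
                 test_variable = test$variable),
            class = "ccgp_result")
}

#' Label-shuffle null for CCGP
#'
#' Permutes left/right labels independently within the train and test
#' contexts, reruns the full repetition procedure per shuffle, and reports
#' the null distribution, the observed CCGP, the deviation direction, and
#' the add-one-corrected tail p-value in the direction of the deviation
#' (above chance: upper tail; below: lower tail).
#'
#' @param train,test `"ccgp_design"` objects.
#' @param n_shuffles Number of label shuffles.
#' @param n_reps Repetitions per shuffle (and for the observed value).
#' @param seed Integer seed.
#' @param cost Margin penalty.
#' @return List: `observed`, `null`, `p`, `direction`
#'   (`"above"`/`"below"`/`"at chance"`), `null_mean`.
#' @export
ccgp_null <- function(train, test, n_shuffles = 500, n_reps = 50, seed = 1,
                      cost = 1) {
  obs <- ccgp(train, test, n_reps = n_reps, seed = child_seed(seed, "obs"),
              cost = cost)$ccgp
  null <- with_seed(child_seed(seed, "ccgp-null", train$variable,
                               test$variable), {
    vapply(seq_len(n_shuffles), function(s) {
      tr <- train; te <- test
      tr$labels <- sample(tr$labels)
      te$labels <- sample(te$labels)
      ccgp(tr, te, n_reps = n_reps,
           seed = child_seed(seed, "shuffle", s), cost = cost)$ccgp
    }, numeric(1))
  })
  dir <- if (obs >= 0.5) "above" else "below"
  p <- if (dir == "above") (1 + sum(null >= obs)) / (n_shuffles + 1)
       else (1 + sum(null <= obs)) / (n_shuffles + 1)
  if (p > 0.05) dir <- "at chance"
  list(observed = obs, null = null, p = p, direction = dir,
       null_mean = mean(null))
}

#' Decoding-axis geometry across variables
#'
#' Trains one linear maximum-margin classifier per variable on its full
#' z-scored design, unit-normalizes the weight vectors (decoding axes),
#' and summarizes their geometry: pairwise cosines, angles in degrees, the
#' cosine-distance matrix `D_ij = sqrt(2 (1 - cos theta_ij))`, and a 2-D
#' classical (Torgerson) MDS embedding of `D` (defined up to rotation and
#' reflection).
#'
#' @param designs Named list of `"ccgp_design"` objects (>= 2).
#' @param cost Margin penalty.
#' @return An `"axis_geometry"`: `axes` (`neurons x variables`), `cosines`,
#'   `angles_deg`, `D`, `mds` (`variables x 2`).
#' @export
axis_geometry <- function(designs, cost = 1) {
  stopifnot(length(designs) >= 2)
  vars <- names(designs)
  axes <- sapply(designs, function(d) {
    z <- scale(d$X)
    z[, attr(z, "scaled:scale") == 0] <- 0
    w <- fit_linear_svm(z, d$labels, cost)$w
    w / sqrt(sum(w^2))
  })
  colnames(axes) <- vars
  cosines <- crossprod(axes)
  cosines <- pmin(pmax(cosines, -1), 1)
  D <- sqrt(pmax(2 * (1 - cosines), 0))
  diag(D) <- 0
  mds <- stats::cmdscale(D, k = min(2L, nrow(D) - 1L))
  while (ncol(mds) < 2) mds <- cbind(mds, 0)
  rownames(mds) <- vars
  structure(list(axes = axes, cosines = cosines,
                 angles_deg = acos(cosines) * 180 / pi, D = D, mds = mds),
            class = "axis_geometry")
}
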