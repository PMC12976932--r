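# Hartigan's dip statistic for unimodality, computed by the greatest convex
# minorant / least concave majorant construction on a shrinking modal
# interval. Jump conventions: the minorant is fitted to the pre-jump ecdf
# values (j - 1 at the first index of each distinct x) and the majorant to
# the post-jump values (j at the last index), so that the two canonical exact
# cases hold: dip = 1/(2n) for any unimodally fittable sample (e.g. equally
# spaced points) and dip = 1/4 for a balanced two-point mass.

# Piecewise-linear interpolation of a touchpoint curve at positions xs.
pl_interp <- function(tx, ty, xs) {
  if (length(tx) == 1) return(rep(ty, length(xs)))
  stats::approx(tx, ty, xout = xs, rule = 2, ties = "ordered")$y
}

# Touch indices (into the sorted sample) of the greatest convex minorant of
# points (x[first index per distinct x], value), by Andrew-monotone-chain.
lower_hull <- function(px, py, idx) {
  h <- integer(0)
  for (i in seq_along(px)) {
    while (length(h) >= 2) {
      a <- h[length(h) - 1]; b <- h[length(h)]
      # drop b if it lies above segment a-i
      if ((py[b] - py[a]) * (px[i] - px[a]) >=
          (py[i] - py[a]) * (px[b] - px[a])) h <- h[-length(h)] else break
    }
    h <- c(h, i)
  }
  idx[h]
}

#' Hartigan's dip statistic
#'
#' The dip is the largest deviation between the empirical CDF and the closest
#' unimodal CDF, computed by iteratively shrinking a candidate modal interval
#' bracketed by the greatest convex minorant (left, rising limb) and least
#' concave majorant (right, falling limb) of the ecdf. Ranges from `1/(2n)`
#' (perfectly unimodal-fittable) to `1/4` (balanced two-point mass).
#'
#' @param x Numeric sample.
#' @return The dip statistic.
#' @export
dip_statistic <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2 || x[1] == x[n]) return(0)
  low <- 1L; high <- n
  D <- 1 # count units; final dip = D / (2n)
  for (iter in 1:100) {
    xs <- x[low:high]
    ux <- unique(xs)
    if (length(ux) == 1) break
    first <- low - 1L + match(ux, xs)              # first index per distinct x
    last <- low - 1L + length(xs) + 1L - match(ux, rev(xs)) # last index
    gcm <- lower_hull(ux, first - 1, first)        # minorant of (x, j - 1)
    lcm <- lower_hull(ux, -as.numeric(last), last) # majorant of (x, j)
    gcm_at <- function(xq) pl_interp(x[gcm], gcm - 1, xq)
    lcm_at <- function(xq) pl_interp(x[lcm], as.numeric(lcm), xq)
    tpx <- sort(unique(c(x[gcm], x[lcm])))
    gap <- lcm_at(tpx) - gcm_at(tpx)
    d <- max(gap)
    if (d <= D) break
    xstar <- tpx[which.max(gap)]
    ix <- max(gcm[x[gcm] <= xstar])   # new low: gcm touch left of the gap
    iv <- min(lcm[x[lcm] >= xstar])   # new high: lcm touch right of the gap
    jl <- low:ix
    dl <- if (length(jl)) max(jl - gcm_at(x[jl])) else 0
    ju <- iv:high
    du <- if (length(ju)) max(lcm_at(x[ju]) - (ju - 1)) else 0
    D <- max(D, dl, du)
    if (ix == low && iv == high) break
    low <- ix; high <- iv
  }
  D / (2 * n)
}

# Cache of uniform-null dip draws, keyed by "n.n_boot.seed" (the null
# distribution of the dip depends on the sample size only).
.dip_null_cache <- new.env(parent = emptyenv())

#' Bootstrap dip null distribution under the uniform
#'
#' @param n Sample size.
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed.
#' @return Numeric vector of `n_boot` dip statistics of uniform samples.
#' @export
dip_null_distribution <- function(n, n_boot = 2000, seed = 1) {
  key <- paste(n, n_boot, seed, sep = ".")
  if (!is.null(.dip_null_cache[[key]])) return(.dip_null_cache[[key]])
  out <- with_seed(child_seed(seed, "dip-null", n, n_boot), {
    vapply(seq_len(n_boot), function(i)
      dip_statistic(stats::runif(n)), numeric(1))
  })
  .dip_null_cache[[key]] <- out
  out
}

#' Hartigan dip test of unimodality
#'
#' Tests the sample against the classical uniform-null bootstrap calibration:
#' the p-value is the (add-one corrected) fraction of uniform-sample dips at
#' the same `n` that reach the observed dip.
#'
#' @param x Numeric sample (`n >= 4` recommended).
#' @param n_boot Bootstrap draws for the null.
#' @param seed Integer seed for the null draws.
#' @return List with `statistic` and `p_value`.
#' @export
dip_test <- function(x, n_boot = 2000, seed = 1) {
  x <- x[is.finite(x)]
  stat <- dip_statistic(x)
  null <- dip_null_distribution(length(x), n_boot, seed)
  list(statistic = stat,
       p_value = (1 + sum(null >= stat)) / (n_boot + 1))
}
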