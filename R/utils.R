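# Internal helpers: reproducible child seeds, the 6x6 spatial grid, Gaussian
# map smoothing, and z-scoring.

# Derive a deterministic child seed from a root seed and a stream label, so
# that e.g. adding neurons never perturbs the behavioural random stream.
# Arithmetic stays below 2^53 so it is exact in doubles; result is in
# [1, 2^31 - 2], a valid set.seed() input.
child_seed <- function(root, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- (as.numeric(root) %% m + 1)
  for (part in list(...)) {
    for (tok in utf8ToInt(paste0(part, "|"))) {
      h <- (h * 69069 + tok) %% m
    }
  }
  as.integer(h %% (m - 1) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Spatial grid over the task field
#'
#' Builds the bin-edge description of the `nx` x `ny` grid (default 6 x 6)
#' used for all spatial binning. Binning is half-open `[edge, next_edge)` with
#' the last bin closed, origin at the bottom-left of the screen. Bin indices
#' are 1-based and row-major: `bin = (row - 1) * nx + col`, where `row`
#' indexes y (bottom row = 1) and `col` indexes x (leftmost = 1).
#'
#' @param field_width,field_height Field extent in pixels.
#' @param nx,ny Number of columns (x) and rows (y).
#' @return An object of class `"spatial_grid"`.
#' @export
spatial_grid <- function(field_width = 1800, field_height = 1000,
                         nx = 6, ny = 6) {
  stopifnot(field_width > 0, field_height > 0, nx >= 1, ny >= 1)
  structure(list(
    field_width = field_width, field_height = field_height,
    nx = nx, ny = ny,
    x_edges = seq(0, field_width, length.out = nx + 1),
    y_edges = seq(0, field_height, length.out = ny + 1)
  ), class = "spatial_grid")
}

n_bins <- function(grid) grid$nx * grid$ny

# Map (x, y) to 1-based row-major bin index; NA propagates.
grid_bin_index <- function(grid, x, y) {
  col <- findInterval(x, grid$x_edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  row <- findInterval(y, grid$y_edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  out <- (row - 1L) * grid$nx + col
  bad <- !is.na(out) & (col < 1L | col > grid$nx | row < 1L | row > grid$ny)
  out[bad] <- NA_integer_
  as.integer(out)
}

# (row, col) coordinates of each bin, in bin units (1-based).
bin_coords <- function(grid) {
  idx <- seq_len(n_bins(grid))
  col <- (idx - 1L) %% grid$nx + 1L
  row <- (idx - 1L) %/% grid$nx + 1L
  cbind(row = row, col = col)
}

#' Gaussian smoothing operator for vectorized rate maps
#'
#' Returns the `nbins x nbins` linear operator that smooths a vectorized map
#' with an isotropic Gaussian of standard deviation `sigma` (in bin units).
#' The kernel is truncated at the field boundary and normalized per *source*
#' bin, so smoothing redistributes each bin's mass without loss: column sums
#' are exactly 1 and total map mass is preserved.
#'
#' @param grid A [spatial_grid()].
#' @param sigma Kernel SD in bin units; `0` returns the identity.
#' @param support Optional logical vector marking source bins to draw from
#'   (used for empty-bin imputation); defaults to all bins.
#' @return A dense matrix `S` such that `smoothed <- S %*% map`.
#' @export
smoothing_matrix <- function(grid, sigma = 0.5, support = NULL) {
  nb <- n_bins(grid)
  if (sigma <= 0) return(diag(nb))
  rc <- bin_coords(grid)
  d2 <- outer(rc[, "row"], rc[, "row"], "-")^2 +
    outer(rc[, "col"], rc[, "col"], "-")^2
  K <- exp(-d2 / (2 * sigma^2))
  if (!is.null(support)) K[!support, ] <- 0
  cs <- colSums(K)
  cs[cs == 0] <- 1
  sweep(K, 2, cs, "/")
}

# Impute empty bins from occupied ones with a truncated Gaussian-weighted
# average (rows = targets, cols = occupied sources, per-target normalized).
impute_empty_bins <- function(values, occupied, grid, sigma) {
  if (all(occupied)) return(values)
  if (!any(occupied)) stop("cannot impute a map with no occupied bins")
  sig <- if (sigma > 0) sigma else 1
  rc <- bin_coords(grid)
  tgt <- which(!occupied); src <- which(occupied)
  d2 <- outer(rc[tgt, "row"], rc[src, "row"], "-")^2 +
    outer(rc[tgt, "col"], rc[src, "col"], "-")^2
  W <- exp(-d2 / (2 * sig^2))
  values[tgt] <- as.vector(W %*% values[src]) / rowSums(W)
  values
}

# Row z-score with n-1 denominator; rows with SD < tol are flagged.
zscore_rows <- function(M, tol = 1e-12) {
  mu <- rowMeans(M)
  sdv <- apply(M, 1, stats::sd)
  flat <- sdv < tol
  Z <- (M - mu) / ifelse(flat, 1, sdv)
  list(Z = Z, zero_variance = flat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
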