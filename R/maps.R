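# Occupancy-binned, Gaussian-smoothed spatial rate maps and z-scored
# population matrices: the common substrate of similarity, subspace and CCGP
# analyses.

#' Bin a trajectory into grid indices over selected trials
#'
#' Assigns each frame of one variable's trajectory to a 1-based row-major bin
#' of `grid`. Only frames that are valid and fall inside trials passing
#' `trial_filter` (default: trials ending in capture, which is how sessions
#' are concatenated for analysis) receive a bin; all other frames are `NA`.
#'
#' @param session A [simulate_session()] result (or [read_session()]).
#' @param variable Variable name in `session$traj`.
#' @param grid A [spatial_grid()]; defaults to the session field.
#' @param trial_filter Function mapping the trial table to a logical vector,
#'   or `NULL` to keep every trial.
#' @return A `"bin_series"`: integer `bin` per frame (`NA` = excluded),
#'   `grid`, `variable`, and `n_included`.
#' @export
bin_position <- function(session, variable, grid = NULL,
                         trial_filter = function(tr) tr$outcome == "captured") {
  stopifnot(variable %in% names(session$traj))
  if (is.null(grid))
    grid <- spatial_grid(session$config$field_width %||% 1800,
                         session$config$field_height %||% 1000)
  tr <- session$traj[[variable]]
  keep <- rep(FALSE, session$n_frames)
  tt <- session$trials
  sel <- if (is.null(trial_filter)) rep(TRUE, nrow(tt)) else trial_filter(tt)
  for (i in which(sel)) keep[tt$start_frame[i]:tt$end_frame[i]] <- TRUE
  bin <- grid_bin_index(grid, tr$x, tr$y)
  bin[!tr$valid | !keep] <- NA_integer_
  n_inc <- sum(!is.na(bin))
  if (n_inc == 0)
    structure(list(bin = bin, grid = grid, variable = variable,
                   n_included = 0L, empty = TRUE), class = "bin_series")
  else
    structure(list(bin = bin, grid = grid, variable = variable,
                   n_included = n_inc, empty = FALSE), class = "bin_series")
}

#' Occupancy-binned, smoothed spatial rate map for one neuron
#'
#' Per-bin firing rate = total spikes in the bin / (occupancy x `frame_dt`),
#' in Hz. Bins never visited are imputed with a truncated-Gaussian weighted
#' average of the occupied bins (the imputation mask is returned), then the
#' map is smoothed with a mass-preserving truncated Gaussian kernel of SD
#' `smoothing_sd` bins (`0` = no smoothing).
#'
#' @param counts Integer spike counts per frame (one neuron).
#' @param bins A [bin_position()] result.
#' @param frame_dt Frame duration, s.
#' @param smoothing_sd Gaussian kernel SD in bin units.
#' @return A `"rate_map"`: `values` (length 36, Hz), `raw` (pre-smoothing),
#'   `occupancy` (frame counts), `imputed` mask, `grid`, `smoothing_sd`.
#' @export
compute_rate_map <- function(counts, bins, frame_dt, smoothing_sd = 0.5) {
  stopifnot(length(counts) == length(bins$bin))
  if (bins$empty || all(is.na(bins$bin)))
    stop("all bins empty: no included frames to map")
  nb <- n_bins(bins$grid)
  ok <- !is.na(bins$bin)
  occ <- tabulate(bins$bin[ok], nbins = nb)
  spk <- rep(0, nb)
  s <- rowsum(as.numeric(counts[ok]), group = bins$bin[ok])
  spk[as.integer(rownames(s))] <- s[, 1]
  raw <- ifelse(occ > 0, spk / (occ * frame_dt), NA_real_)
  imputed <- occ == 0
  raw_f <- impute_empty_bins(ifelse(imputed, 0, raw), occ > 0, bins$grid,
                             smoothing_sd)
  vals <- as.vector(smoothing_matrix(bins$grid, smoothing_sd) %*% raw_f)
  structure(list(values = vals, raw = raw_f, occupancy = occ,
                 imputed = imputed, grid = bins$grid,
                 variable = bins$variable, smoothing_sd = smoothing_sd),
            class = "rate_map")
}

#' Rate maps for all neurons and one variable
#'
#' Convenience wrapper over [compute_rate_map()] for a spike matrix.
#'
#' @param spikes `frames x neurons` count matrix (with `frame_dt` attribute,
#'   or pass `frame_dt`).
#' @param bins A [bin_position()] result.
#' @param frame_dt Frame duration; defaults to the spike matrix attribute.
#' @param smoothing_sd Kernel SD in bins.
#' @return List of `"rate_map"` objects, one per neuron column.
#' @export
rate_maps <- function(spikes, bins, frame_dt = attr(spikes, "frame_dt"),
                      smoothing_sd = 0.5) {
  stopifnot(!is.null(frame_dt))
  lapply(seq_len(ncol(spikes)), function(i)
    compute_rate_map(spikes[, i], bins, frame_dt, smoothing_sd))
}

#' Stack rate maps into a z-scored population matrix
#'
#' Row `i` is neuron `i`'s vectorized (row-major) smoothed map, z-scored
#' across the 36 bins with the `n - 1` denominator. Rows with SD below
#' `1e-12` are flagged as zero-variance and left centered-but-unscaled; by
#' default downstream geometry should drop them (see `zero_variance`).
#'
#' @param maps List of `"rate_map"` objects (one variable, shared grid), or a
#'   plain `neurons x 36` matrix of map values.
#' @param neuron_ids Optional ids; duplicates are an error.
#' @return A `"population_matrix"`: `M` (z-scored), `raw`, `neuron_ids`,
#'   `zero_variance`, `variable`.
#' @export
build_population_matrix <- function(maps, neuron_ids = NULL) {
  if (is.matrix(maps)) {
    raw <- maps
    variable <- attr(maps, "variable") %||% NA_character_
  } else {
    variable <- unique(vapply(maps, `[[`, character(1), "variable"))
    stopifnot(length(variable) == 1)
    raw <- do.call(rbind, lapply(maps, `[[`, "values"))
  }
  if (is.null(neuron_ids)) neuron_ids <- seq_len(nrow(raw))
  if (anyDuplicated(neuron_ids)) stop("duplicate neuron_id")
  z <- zscore_rows(raw)
  structure(list(M = z$Z, raw = raw, neuron_ids = neuron_ids,
                 zero_variance = z$zero_variance, variable = variable),
            class = "population_matrix")
}

# Z-scored matrix with zero-variance rows dropped (shared neuron set must be
# handled by the caller when comparing variables).
pm_matrix <- function(pm, drop_flat = TRUE) {
  if (inherits(pm, "population_matrix")) {
    M <- pm$M
    if (drop_flat && any(pm$zero_variance)) M <- M[!pm$zero_variance, , drop = FALSE]
    M
  } else as.matrix(pm)
}

#' One-call population matrices for several variables
#'
#' Bins each variable, maps every neuron, and returns aligned
#' `population_matrix` objects (same neuron set and order across variables).
#'
#' @param session Session object.
#' @param spikes Spike count matrix.
#' @param variables Variables to map; default all in the session.
#' @param grid,smoothing_sd,trial_filter Passed through.
#' @return Named list of `"population_matrix"` objects.
#' @export
population_matrices <- function(session, spikes,
                                variables = names(session$traj),
                                grid = NULL, smoothing_sd = 0.5,
                                trial_filter = function(tr)
                                  tr$outcome == "captured") {
  out <- lapply(variables, function(v) {
    b <- bin_position(session, v, grid = grid, trial_filter = trial_filter)
    build_population_matrix(rate_maps(spikes, b, smoothing_sd = smoothing_sd))
  })
  names(out) <- variables
  out
}
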