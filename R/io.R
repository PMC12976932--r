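# Session serialization: one directory per session with trajectories.csv,
# spikes.csv (sparse triplets, zeros omitted), trials.csv, config.json and
# optionally ground_truth.json. Comma-separated, UTF-8, header row, '.'
# decimal, floats at 9 significant digits.

fmt_num <- function(x) ifelse(is.na(x), "", formatC(x, digits = 9,
                                                    format = "g"))

#' Write a session (and spikes) to a directory
#'
#' @param session A session object.
#' @param dir Output directory (created if needed).
#' @param spikes Optional `frames x neurons` count matrix.
#' @param population Optional planted population; a compact summary is
#'   stored as `ground_truth.json`.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, spikes = NULL, population = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(session$traj), function(v) {
    tr <- session$traj[[v]]
    data.frame(frame = seq_len(session$n_frames),
               t_s = fmt_num(session$t_s), variable = v,
               x_px = fmt_num(tr$x), y_px = fmt_num(tr$y),
               valid = as.integer(tr$valid))
  })
  utils::write.csv(do.call(rbind, rows),
                   file.path(dir, "trajectories.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE, quote = FALSE)
  if (is.null(spikes)) spikes <- matrix(0L, session$n_frames, 0)
  nz <- which(spikes != 0, arr.ind = TRUE)
  spk <- data.frame(frame = nz[, 1], neuron_id = nz[, 2],
                    count = spikes[nz])
  spk <- spk[order(spk$frame, spk$neuron_id), , drop = FALSE]
  utils::write.csv(spk, file.path(dir, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- session$config
  cfg_out <- c(unclass(cfg), list(n_neurons = ncol(spikes),
                                  n_frames = session$n_frames))
  cfg_out$init_positions <- NULL
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(population)) {
    gt <- list(n_neurons = population$n_neurons,
               variables = population$variables,
               baseline_hz = population$baseline_hz,
               tuned = population$tuned,
               weights = lapply(population$weights, function(w)
                 unname(split(w, row(w)))),
               seed = population$seed)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

stop_schema <- function(file, row, msg) {
  stop("schema error in ", file,
       if (!is.na(row)) paste0(" (row ", row, ")"), ": ", msg, call. = FALSE)
}

#' Read a session directory
#'
#' Validates frame alignment across the three CSVs (a spike row referencing
#' a frame outside the trajectory frame base is an error naming the row),
#' monotone time, and required columns; invalid-position frames are kept as
#' missing.
#'
#' @param dir Session directory written by [write_session()] (or matching
#'   its schema).
#' @return List with `session` (a `"pursuit_session"`) and `spikes`
#'   (`frames x neurons` matrix with `frame_dt` attribute).
#' @export
read_session <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop_schema(f, NA, "file missing")
    p
  }
  traj <- utils::read.csv(need("trajectories.csv"))
  req <- c("frame", "t_s", "variable", "x_px", "y_px", "valid")
  miss <- setdiff(req, names(traj))
  if (length(miss))
    stop_schema("trajectories.csv", NA,
                paste("missing column(s):", paste(miss, collapse = ", ")))
  trials <- utils::read.csv(need("trials.csv"))
  reqt <- c("trial_id", "start_frame", "end_frame", "outcome",
            "chosen_prey_id", "reward")
  miss <- setdiff(reqt, names(trials))
  if (length(miss))
    stop_schema("trials.csv", NA,
                paste("missing column(s):", paste(miss, collapse = ", ")))
  spk <- utils::read.csv(need("spikes.csv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)

  vars <- unique(traj$variable)
  n_frames <- max(traj$frame)
  tlist <- vector("list", length(vars)); names(tlist) <- vars
  t_s <- rep(NA_real_, n_frames)
  for (v in vars) {
    sub <- traj[traj$variable == v, , drop = FALSE]
    if (nrow(sub) != n_frames)
      stop_schema("trajectories.csv", NA,
                  paste0("variable ", v, " has ", nrow(sub),
                         " frames; expected ", n_frames))
    sub <- sub[order(sub$frame), , drop = FALSE]
    tlist[[v]] <- list(x = sub$x_px, y = sub$y_px,
                       valid = as.logical(sub$valid))
    t_s[sub$frame] <- sub$t_s
  }
  if (any(diff(t_s) <= 0))
    stop_schema("trajectories.csv", which(diff(t_s) <= 0)[1] + 1,
                "time not strictly increasing")
  if (nrow(spk) > 0) {
    bad <- which(spk$frame < 1 | spk$frame > n_frames)
    if (length(bad))
      stop_schema("spikes.csv", bad[1],
                  paste("unknown frame", spk$frame[bad[1]]))
  }
  n_neurons <- max(cfg$n_neurons %||% 0,
                   if (nrow(spk)) max(spk$neuron_id) else 0)
  spikes <- matrix(0L, n_frames, n_neurons)
  if (nrow(spk) > 0)
    spikes[cbind(spk$frame, spk$neuron_id)] <- spk$count
  if (n_neurons == 0)
    warning("empty spikes.csv: session has zero-count neurons")
  frame_dt <- cfg$frame_dt %||% stats::median(diff(t_s))
  attr(spikes, "frame_dt") <- frame_dt
  session <- structure(list(
    config = cfg, frame_dt = frame_dt, n_frames = n_frames, t_s = t_s,
    traj = tlist, trials = trials
  ), class = "pursuit_session")
  list(session = session, spikes = spikes)
}
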