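# End-to-end orchestration: simulate (or read) a session, then run the map,
# encoding-model, similarity, subspace and CCGP stages in dependency order,
# writing per-stage outputs, a collated report and a run manifest.

#' Pipeline configuration
#'
#' Assembles and validates the full analysis configuration. Unknown stage
#' names or argument names are rejected. Every run writes the resolved
#' configuration next to its outputs.
#'
#' @param stages Stages to run, in dependency order; any subset of
#'   `c("simulate", "maps", "glm", "similarity", "subspaces", "ccgp")`.
#' @param seed Root seed; all stage randomness derives from it.
#' @param out_dir Output directory.
#' @param session_dir Existing session to read instead of simulating.
#' @param simulate Simulation options: `n_trials`, `n_neurons`, `gaze`
#'   (logical), plus any [plant_population()] arguments under `population`.
#' @param maps Map options: `smoothing_sd`.
#' @param glm GLM options: `candidates`, `alpha`, `beta_grid`, `n_folds`,
#'   `max_neurons` (cap for the encoding stage).
#' @param similarity Similarity options: `n_perm`, `n_splits` (noise
#'   ceiling), `pairs` (list of variable pairs; default all).
#' @param subspaces Subspace options: `k`, `d`, `n_null`, `n_starts`.
#' @param ccgp CCGP options: `chunk_s`, `n_reps`, `n_shuffles`, `pairs`.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(stages = c("simulate", "maps", "glm",
                                       "similarity", "subspaces", "ccgp"),
                            seed = 1, out_dir = tempfile("pursuitgeom-run-"),
                            session_dir = NULL,
                            simulate = list(), maps = list(), glm = list(),
                            similarity = list(), subspaces = list(),
                            ccgp = list()) {
  all_stages <- c("simulate", "maps", "glm", "similarity", "subspaces",
                  "ccgp")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  check <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown ", where, " option(s): ", paste(bad, collapse = ", "))
    given
  }
  cfg <- list(
    stages = stages, seed = seed, out_dir = out_dir,
    session_dir = session_dir,
    simulate = utils::modifyList(
      list(n_trials = 60, n_neurons = 80, gaze = FALSE,
           population = list()),
      check(simulate, c("n_trials", "n_neurons", "gaze", "population"),
            "simulate")),
    maps = utils::modifyList(list(smoothing_sd = 0.5),
                             check(maps, "smoothing_sd", "maps")),
    glm = utils::modifyList(
      list(candidates = NULL, alpha = 0.05, beta_grid = 10^(0:3),
           n_folds = 10, max_neurons = Inf),
      check(glm, c("candidates", "alpha", "beta_grid", "n_folds",
                   "max_neurons"), "glm")),
    similarity = utils::modifyList(
      list(n_perm = 1000, n_splits = 100, pairs = NULL),
      check(similarity, c("n_perm", "n_splits", "pairs"), "similarity")),
    subspaces = utils::modifyList(
      list(k = 10, d = 4, n_null = 1000, n_starts = 5),
      check(subspaces, c("k", "d", "n_null", "n_starts"), "subspaces")),
    ccgp = utils::modifyList(
      list(chunk_s = 40, n_reps = 50, n_shuffles = 100, pairs = NULL),
      check(ccgp, c("chunk_s", "n_reps", "n_shuffles", "pairs"), "ccgp"))
  )
  structure(cfg, class = "pipeline_config")
}

all_pairs <- function(vars) {
  if (length(vars) < 2) return(list())
  cmb <- utils::combn(vars, 2, simplify = FALSE)
  cmb
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order against a simulated or
#' on-disk session, writing per-stage CSV/JSON outputs, a markdown report of
#' headline statistics, the resolved configuration, and a manifest with
#' output hashes, per-stage wall-clock and the seed ledger. Deterministic:
#' identical configurations reproduce identical output hashes.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly; stage results as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- list()
  timings <- list()
  res <- list()
  stage_files <- list()
  report <- c("# pursuitgeom pipeline report", "")
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[3] - t0, 2)
    val
  }

  # --- session -----------------------------------------------------------
  if ("simulate" %in% config$stages) {
    seeds$simulate <- child_seed(config$seed, "simulate")
    sim <- config$simulate
    res$session <- tick("simulate", {
      cfg <- task_config()
      s <- simulate_session(cfg, sim$n_trials, seed = seeds$simulate)
      if (isTRUE(sim$gaze)) s <- simulate_gaze(s, seed = seeds$simulate)
      s
    })
    pop_args <- utils::modifyList(
      list(n_neurons = sim$n_neurons,
           variables = setdiff(names(res$session$traj), "gaze"),
           seed = child_seed(config$seed, "population")),
      sim$population)
    res$population <- do.call(plant_population, pop_args)
    res$spikes <- simulate_spikes(res$session, res$population,
                                  seed = child_seed(config$seed, "spikes"))
    write_session(res$session, file.path(out, "session"), res$spikes,
                  res$population)
    stage_files$simulate <- file.path(out, "session",
                                      c("trajectories.csv", "spikes.csv",
                                        "trials.csv"))
  } else {
    if (is.null(config$session_dir))
      stop("no simulate stage and no session_dir to read")
    rs <- read_session(config$session_dir)
    res$session <- rs$session
    res$spikes <- rs$spikes
  }
  vars <- names(res$session$traj)
  report <- c(report, sprintf(
    "Session: %d frames, %d trials (%d captured), %d neurons, variables: %s",
    res$session$n_frames, nrow(res$session$trials),
    sum(res$session$trials$outcome == "captured"), ncol(res$spikes),
    paste(vars, collapse = ", ")), "")

  # --- maps --------------------------------------------------------------
  if (any(c("maps", "similarity", "subspaces") %in% config$stages)) {
    res$pms <- tick("maps", population_matrices(
      res$session, res$spikes, variables = vars,
      smoothing_sd = config$maps$smoothing_sd))
  }
  if ("maps" %in% config$stages) {
    tab <- do.call(rbind, lapply(vars, function(v) {
      p <- res$pms[[v]]
      data.frame(neuron_id = rep(p$neuron_ids, each = 36), variable = v,
                 bin_index = rep(1:36, length(p$neuron_ids)),
                 rate_hz = as.vector(t(p$raw)))
    }))
    f <- file.path(out, "maps.csv")
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
    stage_files$maps <- f
  }

  # --- glm ---------------------------------------------------------------
  if ("glm" %in% config$stages) {
    g <- config$glm
    cand <- g$candidates %||% vars
    seeds$glm <- child_seed(config$seed, "glm")
    res$tuning <- tick("glm", {
      bins <- lapply(cand, function(v) bin_position(res$session, v))
      names(bins) <- cand
      design <- build_design_matrix(bins)
      nsel <- min(ncol(res$spikes), g$max_neurons)
      lapply(seq_len(nsel), function(i)
        select_model(design, res$spikes[, i], res$session$frame_dt,
                     alpha = g$alpha, beta_grid = g$beta_grid,
                     n_folds = g$n_folds, neuron_id = i))
    })
    tab <- do.call(rbind, lapply(res$tuning, function(tm)
      data.frame(neuron_id = tm$neuron_id, tuned = tm$tuned,
                 selected_variables = paste(tm$selected, collapse = ";"),
                 mean_cv_llh_bits_per_spike = tm$mean_llh)))
    f <- file.path(out, "tuning.csv")
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
    stage_files$glm <- f
    frac <- mean(tab$tuned)
    report <- c(report, sprintf("## Tuning\n%d/%d neurons tuned (%.1f%%)",
                                sum(tab$tuned), nrow(tab), 100 * frac), "")
  }

  # --- similarity --------------------------------------------------------
  if ("similarity" %in% config$stages) {
    s <- config$similarity
    pairs <- s$pairs %||% all_pairs(vars)
    seeds$similarity <- child_seed(config$seed, "similarity")
    res$similarity <- tick("similarity", lapply(pairs, function(pr) {
      a <- res$pms[[pr[1]]]; b <- res$pms[[pr[2]]]
      keep <- !a$zero_variance & !b$zero_variance
      sp <- vapply(which(keep), function(i)
        spaef(a$raw[i, ], b$raw[i, ])$spaef, numeric(1))
      api <- agent_preference_indices(a, b, seed = seeds$similarity)
      list(pair = pr, mean_spaef = mean(sp), spaef = sp,
           api_dip = api$dip, api_dip_p = api$dip_p)
    }))
    tab <- do.call(rbind, lapply(res$similarity, function(x)
      data.frame(pair = paste(x$pair, collapse = "-"),
                 mean_spaef = x$mean_spaef, api_dip = x$api_dip,
                 api_dip_p = x$api_dip_p)))
    f <- file.path(out, "similarity.csv")
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
    stage_files$similarity <- f
    report <- c(report, "## Map similarity",
                paste(utils::capture.output(print(tab)), collapse = "\n"),
                "")
  }

  # --- subspaces ---------------------------------------------------------
  if ("subspaces" %in% config$stages) {
    sb <- config$subspaces
    seeds$subspaces <- child_seed(config$seed, "subspaces")
    res$geometry <- tick("subspaces", {
      keep <- Reduce(`&`, lapply(res$pms, function(p) !p$zero_variance))
      Ms <- lapply(res$pms, function(p) p$M[keep, , drop = FALSE])
      pairs <- all_pairs(vars)
      ai <- lapply(pairs, function(pr)
        alignment_index(Ms[[pr[1]]], Ms[[pr[2]]], k = sb$k,
                        n_null = sb$n_null, seed = seeds$subspaces))
      names(ai) <- vapply(pairs, paste, "", collapse = "-")
      C_list <- lapply(Ms, neuron_cov)
      basis <- optimize_orthogonal_subspaces(C_list, d_list = sb$d,
                                             n_starts = sb$n_starts,
                                             seed = seeds$subspaces)
      coords <- subspace_coordinates(Ms, basis)
      lm <- lapply(pairs, function(pr)
        fit_linear_map(coords[[pr[1]]], coords[[pr[2]]],
                       seed = seeds$subspaces))
      names(lm) <- names(ai)
      list(ai = ai, basis = basis, linear_maps = lm)
    })
    f <- file.path(out, "geometry.json")
    jsonlite::write_json(list(
      alignment = lapply(res$geometry$ai, function(a)
        list(ai = a$ai, p = a$p)),
      var_captured = as.list(res$geometry$basis$var_captured),
      linear_maps = lapply(res$geometry$linear_maps, function(m)
        list(r2_train = m$r2_train, r2_loocv = m$r2_loocv, p = m$p))
    ), f, auto_unbox = TRUE, digits = NA)
    stage_files$subspaces <- f
    report <- c(report, "## Subspace geometry",
                paste(sprintf("- AI(%s) = %.3f (p = %.3g)",
                              names(res$geometry$ai),
                              vapply(res$geometry$ai, `[[`, 0, "ai"),
                              vapply(res$geometry$ai, `[[`, 0, "p")),
                      collapse = "\n"), "")
  }

  # --- ccgp --------------------------------------------------------------
  if ("ccgp" %in% config$stages) {
    cc <- config$ccgp
    seeds$ccgp <- child_seed(config$seed, "ccgp")
    res$ccgp <- tick("ccgp", {
      chunks <- chunk_session(res$session, res$spikes, chunk_s = cc$chunk_s)
      designs <- lapply(vars, function(v) build_ccgp_design(chunks, v))
      names(designs) <- vars
      pairs <- cc$pairs %||% all_pairs(vars)
      runs <- lapply(pairs, function(pr)
        ccgp_null(designs[[pr[1]]], designs[[pr[2]]],
                  n_shuffles = cc$n_shuffles, n_reps = cc$n_reps,
                  seed = seeds$ccgp))
      names(runs) <- vapply(pairs, paste, "", collapse = "->")
      list(designs = designs, runs = runs,
           axes = axis_geometry(designs))
    })
    f <- file.path(out, "ccgp.json")
    jsonlite::write_json(lapply(res$ccgp$runs, function(r)
      list(ccgp = r$observed, p = r$p, direction = r$direction,
           null_mean = r$null_mean)), f, auto_unbox = TRUE, digits = NA)
    stage_files$ccgp <- f
    report <- c(report, "## CCGP",
                paste(sprintf("- %s: %.3f (%s, p = %.3g)",
                              names(res$ccgp$runs),
                              vapply(res$ccgp$runs, `[[`, 0, "observed"),
                              vapply(res$ccgp$runs, `[[`, "", "direction"),
                              vapply(res$ccgp$runs, `[[`, 0, "p")),
                      collapse = "\n"), "")
  }

  # --- manifest ----------------------------------------------------------
  cfg_file <- file.path(out, "config_resolved.json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  writeLines(report, file.path(out, "report.md"))
  files <- unlist(stage_files, use.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pursuitgeom")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed, seed_ledger = seeds,
    stages_run = intersect(config$stages,
                           c("simulate", "maps", "glm", "similarity",
                             "subspaces", "ccgp")),
    stages_skipped = setdiff(c("simulate", "maps", "glm", "similarity",
                               "subspaces", "ccgp"), config$stages),
    file_hashes = as.list(tools::md5sum(files)),
    wall_clock_s = timings
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "results") <- res
  invisible(manifest)
}
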