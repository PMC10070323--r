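# Run configuration, pipeline orchestration and checkpointing.

#' Read and validate a run configuration
#'
#' Plain-text YAML with blocks `system` (name or xyz + spins + units),
#' `trial` (name + parameters + optional checkpoint), `vmc`, `dmc`
#' (sampler parameters, see [vmc_params()] / [dmc_params()]), `stages`
#' (subset of `optimize`, `vmc`, `dmc`), `output_dir` and `seed`.  Every
#' field is validated before any computation starts.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return validated config list of class `fndmc_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$system)) stop("config error: missing 'system' block")
  if (is.null(cfg$trial) || is.null(cfg$trial$name))
    stop("config error: missing 'trial' block with a 'name'")
  cfg$seed <- as.integer(cfg$seed %||% 1)
  cfg$stages <- cfg$stages %||% c("vmc", "dmc")
  bad <- setdiff(cfg$stages, c("optimize", "vmc", "dmc"))
  if (length(bad)) stop("config error: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  cfg$output_dir <- cfg$output_dir %||% "fndmc-run"
  # resolve the system now so errors surface before sampling
  sys <- if (!is.null(cfg$system$xyz)) {
    load_xyz(cfg$system$xyz, n_up = cfg$system$n_up,
             n_down = cfg$system$n_down,
             units = cfg$system$units %||% "angstrom")
  } else if (!is.null(cfg$system$name)) {
    builtin_system(cfg$system$name, cfg$system$params %||% list())
  } else stop("config error: system needs 'name' or 'xyz'")
  cfg$resolved_system <- sys
  # trial construction validates name and parameters
  cfg$resolved_trial <- make_trial(cfg$trial$name, sys,
                                   cfg$trial$params %||% list())
  structure(cfg, class = c("fndmc_config", "list"))
}

#' Run the configured pipeline
#'
#' Executes the requested stages in order (optimize, then VMC inference,
#' then DMC), writing per-stage CSV logs, checkpoints and a machine-
#' readable JSON summary (all energies in Hartree with standard errors,
#' plus diagnostics) into the output directory.  The fully resolved
#' configuration is echoed to `config.yaml` there.  Identical config and
#' seed give an identical summary.
#'
#' @param config a [read_run_config()] result (or a path / list accepted by
#'   it).
#' @return the output directory path, invisibly; the summary list as the
#'   `"summary"` attribute.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "fndmc_config")) config <- read_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  echo <- config
  echo$resolved_system <- NULL; echo$resolved_trial <- NULL
  yaml::write_yaml(echo, file.path(config$output_dir, "config.yaml"))
  sys <- config$resolved_system
  trial <- config$resolved_trial
  seed <- config$seed
  summary <- list(system = sys$label, trial = trial$name, seed = seed,
                  units = list(energy = "Hartree", length = "bohr"))
  vargs <- config$vmc %||% list()
  if (is.null(vargs$seed)) vargs$seed <- seed
  vp <- do.call(vmc_params, vargs)
  if ("optimize" %in% config$stages) {
    opt <- optimize_trial(trial, sys, params = vp,
                          n_iters = config$optimize$n_iters %||% 100,
                          learning_rate = config$optimize$learning_rate %||% 0.05)
    trial <- opt$trial
    utils::write.csv(opt$trajectory,
                     file.path(config$output_dir, "optimize.csv"),
                     row.names = FALSE)
    saveRDS(as.numeric(trial$params),
            file.path(config$output_dir, "trial_checkpoint.rds"))
    summary$optimize <- list(
      n_iters = nrow(opt$trajectory),
      final_energy_Ha = opt$trajectory$energy[nrow(opt$trajectory)],
      diverged = opt$diverged)
  }
  if ("vmc" %in% config$stages) {
    ve <- vmc_energy(trial, sys, params = vp)
    utils::write.csv(
      data.frame(level = ve$block_curve$level,
                 stderr_Ha = ve$block_curve$stderr),
      file.path(config$output_dir, "vmc_reblock.csv"), row.names = FALSE)
    summary$vmc <- list(energy_Ha = ve$mean, stderr_Ha = ve$stderr,
                        acceptance = ve$acceptance)
  }
  if ("dmc" %in% config$stages) {
    dargs <- config$dmc %||% list()
    if (is.null(dargs$seed)) dargs$seed <- seed
    dp <- do.call(dmc_params, dargs)
    dr <- run_dmc(trial, sys, dp)
    utils::write.csv(
      data.frame(iteration = seq_along(dr$energy_series),
                 E_mixed_Ha = dr$energy_series,
                 E_T_Ha = dr$et_series,
                 total_weight = dr$weight_series),
      file.path(config$output_dir, "dmc.csv"), row.names = FALSE)
    save_dmc_state(dr$state, file.path(config$output_dir, "dmc_state.rds"))
    summary$dmc <- c(list(energy_Ha = dr$energy$mean,
                          stderr_Ha = dr$energy$stderr),
                     dr$diagnostics)
  }
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(invisible(config$output_dir), summary = summary)
}

#' Save a DMC state (including the RNG stream) to disk
#'
#' @param state a `fndmc_dmc_state` (as found in `run_dmc()$state`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_dmc_state <- function(state, path) {
  if (is.null(attr(state, "rng_state")) && exists(".Random.seed", globalenv()))
    attr(state, "rng_state") <- get(".Random.seed", envir = globalenv())
  saveRDS(list(format = "fndmc_dmc_state", version = 1L, state = state), path)
  invisible(path)
}

#' Load a DMC state saved by [save_dmc_state()]
#'
#' Restores all walker data bit-exactly, including the RNG stream, so a
#' resumed [run_dmc()] reproduces an unbroken run step for step.
#'
#' @param path file written by [save_dmc_state()].
#' @return a `fndmc_dmc_state`.
#' @export
load_dmc_state <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read DMC checkpoint: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "fndmc_dmc_state"))
    stop("not a DMC checkpoint file: ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported DMC checkpoint version: ", obj$version)
  obj$state
}
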