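# Run configuration: a single YAML file describes a threshold or CSP run
# (molecule files, force field, lid schedule, move spec, RNG seed). Every run
# directory receives a frozen copy of its configuration plus the package
# version, so runs can be reproduced from their outputs alone.

#' Read a run configuration
#'
#' YAML with (all optional unless noted): `molecules` (named map of XYZ file
#' paths; required), `forcefield` (force-field file path; required),
#' `settings` (arguments of [energy_settings()]), `moves` (arguments of
#' [move_spec()]), `schedule` (arguments of [lid_schedule()]), `criteria`
#' (arguments of [match_criteria()]), `seed` (integer).
#' @param path YAML file path
#' @param base_dir directory against which relative paths are resolved
#'   (default: the configuration file's directory)
#' @return list with `molecules`, `ff`, `settings`, `moves`, `schedule`,
#'   `criteria`, `seed`
#' @export
read_run_config <- function(path, base_dir = dirname(path)) {
  cfg <- yaml::read_yaml(path)
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  if (is.null(cfg$molecules) || is.null(cfg$forcefield)) {
    stop("configuration must declare 'molecules' and 'forcefield'")
  }
  molecules <- lapply(cfg$molecules, function(p) read_xyz(resolve(p)))
  ff <- read_forcefield(resolve(cfg$forcefield))
  list(
    molecules = molecules,
    ff = ff,
    settings = do.call(energy_settings, as.list(cfg$settings)),
    moves = do.call(move_spec, as.list(cfg$moves)),
    schedule = if (!is.null(cfg$schedule)) {
      do.call(lid_schedule, as.list(cfg$schedule))
    } else NULL,
    criteria = do.call(match_criteria, as.list(cfg$criteria)),
    seed = if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  )
}

#' Write run provenance
#'
#' Freezes the configuration, RNG seed and package version into a run
#' directory.
#' @param dir run directory (created if missing)
#' @param config_path path of the configuration file to copy
#' @param seed RNG seed used
#' @return `dir`, invisibly
#' @export
write_provenance <- function(dir, config_path = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config_path)) {
    file.copy(config_path, file.path(dir, "config.yaml"), overwrite = TRUE)
  }
  meta <- list(
    package = "xtalmc",
    version = as.character(utils::packageVersion("xtalmc")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(meta, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Write a threshold run's event log
#'
#' Append-only JSON-lines log of the accepted steps of a run, so
#' disconnectivity graphs can be rebuilt without re-simulation.
#' @param run a [run_threshold()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_event_log <- function(run, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(run$log))) {
    row <- run$log[i, ]
    writeLines(sprintf(
      '{"run":%s,"lid_index":%d,"lid_energy":%.8g,"step":%d,"e_unmin":%.8g,"e_min":%.8g,"min_id":%d}',
      run$run_id, row$lid_index, row$lid_energy, row$step, row$e_unmin,
      row$e_min, row$min_id), con)
  }
  invisible(path)
}
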