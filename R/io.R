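#' Write a population series to CSV
#'
#' Columns: t, n_predator, n_prey, captures_pred_action,
#' captures_prey_action, births_pred, births_prey, deaths_starvation,
#' deaths_age (prey), deaths_age_pred.
#'
#' @param series The `series` data frame of [run_episode()].
#' @param path Output path.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Read a population series written by [write_series_csv()]
#' @param path CSV path.
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path)
}

#' Write a state snapshot to JSON
#'
#' Config echo, current step, and per-agent records (id, species, row, col,
#' starvation, age) with 0-based row-major coordinates.
#'
#' @param state A grid state, or a snapshot from [run_episode()].
#' @param path Output path.
#' @export
write_snapshot_json <- function(state, path) {
  ag <- if (!is.null(state$agents)) state$agents else state
  cfg <- state$config
  rec <- list(config = if (is.null(cfg)) NULL else unclass(cfg),
              t = state$t %||% NA_integer_,
              agents = agents_df(list(agents = ag)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a run manifest
#'
#' Records the full configuration, seeds, package version, output paths and
#' a timestamp; a manifest suffices to re-run the experiment.
#'
#' @param dir Output directory.
#' @param env_cfg,train_cfg Configurations (train may be `NULL`).
#' @param seed Master seed of the run.
#' @param outputs Character vector of files produced.
#' @param command Subcommand that produced the run.
#' @export
write_manifest <- function(dir, env_cfg, train_cfg = NULL, seed = NA,
                           outputs = character(0), command = NA_character_) {
  man <- list(package = "ppcoevo",
              version = as.character(utils::packageVersion("ppcoevo")),
              command = command, seed = seed,
              seed_streams = if (is.na(seed)) NULL else seed_streams(seed),
              env = unclass(env_cfg),
              train = if (is.null(train_cfg)) NULL else unclass(train_cfg),
              outputs = outputs, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(man)
}
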