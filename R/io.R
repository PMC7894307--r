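## Output bundle: a directory of CSVs (RFC-4180, UTF-8, "." decimal) plus
## a config echo and a log with seeds and the config hash. CSVs are
## written atomically (temp file + rename). The experiment object itself
## is cached as RDS inside the bundle so the analysis subcommands can be
## re-run without re-simulating.

write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Kill and wind series of an experiment as one long data.frame
#' @param experiment a `bl_experiment`.
#' @export
kill_series_df <- function(experiment) {
  do.call(rbind, lapply(experiment$runs, function(run) {
    data.frame(scenario = run$climate_name,
               disturbed = run$disturbed, replicate = run$replicate,
               year = seq_along(run$annual_kill),
               beetle_kill_m3_ha_yr = run$annual_kill,
               wind_kill_m3_ha_yr = run$annual_wind)
  }))
}

#' Indicator snapshots of an experiment as one long data.frame
#' @param experiment a `bl_experiment`.
#' @export
indicator_series_df <- function(experiment) {
  do.call(rbind, lapply(experiment$runs, function(run) {
    cbind(data.frame(scenario = run$climate_name, disturbed = run$disturbed,
                     replicate = run$replicate), run$indicators)
  }))
}

#' Event logs of an experiment as one long data.frame
#' @param experiment a `bl_experiment`.
#' @export
events_df <- function(experiment) {
  do.call(rbind, lapply(experiment$runs, function(run) {
    if (!nrow(run$events)) return(NULL)
    nr <- run$final_state$nrow
    data.frame(scenario = run$climate_name, replicate = run$replicate,
               year = run$events$year,
               row = ((run$events$cell - 1L) %% nr) + 1L,
               col = ((run$events$cell - 1L) %/% nr) + 1L,
               agent = run$events$agent,
               volume_m3_ha = run$events$volume_m3_ha)
  }))
}

#' Write an experiment bundle to a directory
#'
#' Writes `kill_series.csv`, `indicators.csv`, `events.csv`, a final
#' landscape snapshot per run arm (`landscape_<key>.csv`), `config.yml`
#' (the config echo), `experiment.rds` (cache for analysis subcommands)
#' and `log.txt` (seeds, config hash, wall time).
#'
#' @param experiment a `bl_experiment`.
#' @param dir output directory (created if missing).
#' @param config the configuration that produced the experiment.
#' @param snapshots write per-run final landscape CSVs (default FALSE).
#' @return the directory path, invisibly.
#' @export
write_outputs <- function(experiment, dir, config = default_config(),
                          snapshots = FALSE) {
  t0 <- Sys.time()
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", dir))
  }
  write_csv_atomic(kill_series_df(experiment), file.path(dir, "kill_series.csv"))
  write_csv_atomic(indicator_series_df(experiment), file.path(dir, "indicators.csv"))
  ev <- events_df(experiment)
  if (is.null(ev)) {
    ev <- data.frame(scenario = character(), replicate = integer(),
                     year = integer(), row = integer(), col = integer(),
                     agent = character(), volume_m3_ha = numeric())
  }
  write_csv_atomic(ev, file.path(dir, "events.csv"))
  if (snapshots) {
    for (key in names(experiment$runs)) {
      write_csv_atomic(landscape_to_df(experiment$runs[[key]]$final_state),
                       file.path(dir, paste0("landscape_", key, ".csv")))
    }
  }
  cfg <- config
  attributes(cfg)["hash"] <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  saveRDS(experiment, file.path(dir, "experiment.rds"))
  writeLines(c(
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("base_seed: %d", experiment$design$base_seed),
    sprintf("replicates: %d", experiment$design$replicates),
    sprintf("written: %s", format(t0, "%Y-%m-%d %H:%M:%S"))),
    file.path(dir, "log.txt"))
  invisible(dir)
}
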