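## The factorial experiment: climate scenario x disturbed/undisturbed x
## replicate, each run a 300- or 600-year annual simulation with indicator
## snapshots every 50 years. The disturbed and undisturbed member of a
## replicate pair share the landscape, the climate draw and the vegetation
## RNG stream (common random numbers), so their differences are
## attributable to disturbance alone; disturbance randomness lives on a
## second, independent stream.

#' Scenario specification
#'
#' @param climate one of `"BC"`, `"MC"`, `"HC"`, `"HWC"`.
#' @param disturbed logical: simulate wind + beetle disturbance?
#' @param horizon_yr simulation length, years (divisible by
#'   `indicator_step_yr`).
#' @param indicator_step_yr indicator snapshot interval, years.
#' @param replicates number of replicate runs.
#' @param base_seed integer; replicate r uses seeds derived from
#'   `base_seed + r` (landscape/climate/vegetation/disturbance sub-streams).
#' @return object of class `bl_scenario_spec`.
#' @export
scenario_spec <- function(climate = "BC", disturbed = TRUE, horizon_yr = 300L,
                          indicator_step_yr = 50L, replicates = 5L,
                          base_seed = 42L) {
  if (!climate %in% BL_SCENARIOS) config_error("unknown climate scenario")
  if (horizon_yr %% indicator_step_yr != 0) {
    config_error("horizon_yr must be divisible by indicator_step_yr")
  }
  if (replicates < 1) config_error("replicates must be >= 1")
  structure(list(climate = climate, disturbed = disturbed,
                 horizon_yr = as.integer(horizon_yr),
                 indicator_step_yr = as.integer(indicator_step_yr),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "bl_scenario_spec")
}

## seed offsets for the independent sub-streams of one replicate
rep_seeds <- function(base_seed, rep) {
  list(landscape = base_seed + rep,
       climate = base_seed + 100000L + rep,
       vegetation = base_seed + 200000L + rep,
       disturbance = base_seed + 300000L + rep)
}

#' Run one scenario arm
#'
#' Simulates `replicates` runs of one (climate, disturbed) combination.
#' Undisturbed runs skip wind and beetle steps entirely; vegetation
#' dynamics are identical otherwise.
#'
#' @param spec a [scenario_spec()].
#' @param config configuration list.
#' @return list of run results, one per replicate; each has `annual_kill`
#'   and `annual_wind` (landscape-mean m3/ha/yr), `indicators` (data.frame
#'   of snapshots), `events` (kill/wind logs), `climate` (the annual
#'   climate series) and `final_state`.
#' @export
run_scenario <- function(spec, config = default_config()) {
  lapply(seq_len(spec$replicates), function(rep) {
    simulate_run(spec, config, rep)
  })
}

simulate_run <- function(spec, config, rep) {
  seeds <- rep_seeds(spec$base_seed, rep)
  state <- generate_initial_landscape(config, seeds$landscape)
  climate <- make_climate_scenario(spec$climate, spec$horizon_yr,
                                   seeds$climate, config)
  veg_rng <- rng_stream(seeds$vegetation)
  dist_rng <- rng_stream(seeds$disturbance)
  beetles <- new_beetle_state(state$nrow, state$ncol,
                              config$beetle$background)
  ncell <- state$nrow * state$ncol
  H <- spec$horizon_yr
  kill <- wind <- numeric(H)
  indicators <- indicator_vector(state, config)
  events <- vector("list", H)

  for (y in seq_len(H)) {
    cy <- climate[y, ]
    state <- with_stream(veg_rng,
                         annual_vegetation_step(state, cy, config))
    if (spec$disturbed) {
      res <- with_stream(dist_rng, {
        wres <- apply_wind(state, cy, config)
        bres <- annual_beetle_step(wres$state, cy, wres$events, beetles,
                                   config)
        list(state = bres$state, beetles = bres$beetles,
             wind_events = wres$events, kill_records = bres$records)
      })
      state <- res$state
      beetles <- res$beetles
      kill[y] <- sum(res$kill_records$volume_m3_ha) / ncell
      wind[y] <- sum(res$wind_events$downed_total_volume_m3_ha) / ncell
      ev <- list()
      if (nrow(res$wind_events)) {
        ev$wind <- data.frame(year = res$wind_events$year,
                              cell = res$wind_events$cell, agent = "wind",
                              volume_m3_ha = res$wind_events$downed_total_volume_m3_ha)
      }
      if (nrow(res$kill_records)) ev$beetle <- res$kill_records
      if (length(ev)) events[[y]] <- do.call(rbind, unname(ev))
    }
    if (y %% spec$indicator_step_yr == 0) {
      indicators <- rbind(indicators, indicator_vector(state, config))
    }
    validate_landscape(state, ba_cap = config$vegetation$ba_cap + 20)
  }
  events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(year = integer(), cell = integer(),
                         agent = character(), volume_m3_ha = numeric())
  }
  list(climate_name = spec$climate, disturbed = spec$disturbed,
       replicate = rep, annual_kill = kill, annual_wind = wind,
       indicators = indicators, events = events,
       climate = as.data.frame(climate), final_state = state)
}

#' Run the full factorial experiment
#'
#' All requested climate scenarios, disturbed and undisturbed arms, all
#' replicates. Replicate pairs share seeds across arms.
#'
#' @param config configuration list; section `experiment` supplies the
#'   design (climates, horizon, step, replicates, base seed).
#' @return object of class `bl_experiment`: list with `runs` (a named list,
#'   keys `"<climate>_<disturbed|undisturbed>_<rep>"`) and `design`.
#' @export
run_experiment <- function(config = default_config()) {
  ex <- config$experiment
  runs <- list()
  for (cl in ex$climates) {
    for (dist in c(TRUE, FALSE)) {
      spec <- scenario_spec(cl, dist, ex$horizon_yr, ex$indicator_step_yr,
                            ex$replicates, ex$base_seed)
      rr <- run_scenario(spec, config)
      for (r in seq_along(rr)) {
        runs[[run_key(cl, dist, r)]] <- rr[[r]]
      }
    }
  }
  structure(list(runs = runs, design = ex,
                 config_hash = config_hash(config)),
            class = "bl_experiment")
}

run_key <- function(climate, disturbed, rep) {
  sprintf("%s_%s_%d", climate, if (disturbed) "disturbed" else "undisturbed",
          rep)
}

#' Fetch one run from an experiment
#' @param experiment a `bl_experiment`.
#' @param climate,disturbed,rep arm coordinates.
#' @export
get_run <- function(experiment, climate, disturbed, rep) {
  key <- run_key(climate, disturbed, rep)
  if (is.null(experiment$runs[[key]])) {
    stop(sprintf("run '%s' not present in the experiment", key))
  }
  experiment$runs[[key]]
}

#' @export
print.bl_experiment <- function(x, ...) {
  cat(sprintf("<bl_experiment> %d runs (%s; %d yr, %d replicates)\n",
              length(x$runs), paste(x$design$climates, collapse = "/"),
              x$design$horizon_yr, x$design$replicates))
  invisible(x)
}

#' Exponential moving average of an annual series
#'
#' \eqn{y_t = \alpha x_t + (1-\alpha) y_{t-1}} with \eqn{y_1 = x_1}; the
#' 10-year window with reduction factor 1/10 corresponds to
#' `alpha = 0.1`.
#'
#' @param annual numeric series.
#' @param alpha smoothing fraction in (0, 1].
#' @return series of the same length.
#' @export
ema_series <- function(annual, alpha = 0.1) {
  if (!length(annual)) stop("empty series")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  as.numeric(stats::filter(alpha * annual, 1 - alpha, method = "recursive",
                           init = annual[1]))
}

#' Reference bark beetle activity of the recent past
#'
#' The observed 10-year exponential moving average of bark beetle
#' disturbance 1990-2010 on the reference landscape, m3/ha/yr; used as a
#' horizontal reference line when plotting simulated EMA curves.
#' @export
BL_REFERENCE_EMA <- 10.73

#' Plot smoothed beetle-kill trajectories per climate scenario
#'
#' Draws the replicate-mean exponential moving average of the annual
#' beetle-killed volume for each climate scenario's disturbed arm, with a
#' shaded replicate range and the recent-past reference level
#' ([BL_REFERENCE_EMA]) as a dashed line.
#'
#' @param experiment a `bl_experiment`.
#' @param alpha EMA smoothing fraction.
#' @param file optional PNG path; if given the plot is written there.
#' @return invisibly, a data.frame of the plotted mean EMA series.
#' @export
plot_kill_ema <- function(experiment, alpha = 0.1, file = NULL) {
  des <- experiment$design
  cols <- stats::setNames(c("grey30", "goldenrod3", "orangered3", "purple3"),
                          c("BC", "MC", "HC", "HWC"))
  series <- lapply(des$climates, function(cl) {
    e <- vapply(seq_len(des$replicates), function(r) {
      ema_series(get_run(experiment, cl, TRUE, r)$annual_kill, alpha)
    }, numeric(des$horizon_yr))
    list(mean = rowMeans(e), lo = apply(e, 1, min), hi = apply(e, 1, max))
  })
  names(series) <- des$climates
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 560)
    on.exit(grDevices::dev.off())
  }
  ylim <- c(0, max(vapply(series, function(s) max(s$hi), numeric(1))))
  plot(NULL, xlim = c(1, des$horizon_yr), ylim = ylim,
       xlab = "simulation year",
       ylab = sprintf("beetle kill, %d-yr EMA (m3/ha/yr)", round(1 / alpha)))
  for (cl in des$climates) {
    s <- series[[cl]]
    graphics::polygon(c(seq_along(s$lo), rev(seq_along(s$hi))),
                      c(s$lo, rev(s$hi)),
                      col = grDevices::adjustcolor(cols[[cl]], 0.15),
                      border = NA)
    graphics::lines(s$mean, col = cols[[cl]], lwd = 2)
  }
  graphics::abline(h = BL_REFERENCE_EMA, lty = 2)
  graphics::legend("topright", legend = des$climates, col = cols[des$climates],
                   lwd = 2, bty = "n")
  invisible(data.frame(year = seq_len(des$horizon_yr),
                       lapply(series, `[[`, "mean")))
}

arm_cumulative_kill <- function(experiment, climate) {
  reps <- experiment$design$replicates
  vapply(seq_len(reps), function(r) {
    sum(get_run(experiment, climate, TRUE, r)$annual_kill)
  }, numeric(1))
}

#' Cumulative beetle-kill contrast between two climate scenarios
#'
#' Percent difference of the replicate-mean cumulative beetle-killed
#' volume of the disturbed arms,
#' \eqn{100 (\overline{\Sigma kill}_a - \overline{\Sigma kill}_b) /
#' \overline{\Sigma kill}_b}, with a bootstrap CI over replicates, plus
#' the fraction of each scenario's cumulative kill accruing in the first
#' 200 simulation years.
#'
#' @param experiment a `bl_experiment` containing both disturbed arms.
#' @param climate_a,climate_b scenario names (a is contrasted against b).
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @return list with `percent`, `ci`, `mean_a`, `mean_b`,
#'   `frac_first200_a`, `frac_first200_b`.
#' @export
cumulative_contrast <- function(experiment, climate_a, climate_b,
                                n_boot = 1000, conf = 0.95) {
  ka <- arm_cumulative_kill(experiment, climate_a)
  kb <- arm_cumulative_kill(experiment, climate_b)
  pct <- function(a, b) 100 * (mean(a) - mean(b)) / mean(b)
  boot <- replicate(n_boot, {
    pct(sample(ka, replace = TRUE), sample(kb, replace = TRUE))
  })
  frac200 <- function(climate) {
    reps <- experiment$design$replicates
    f <- vapply(seq_len(reps), function(r) {
      k <- get_run(experiment, climate, TRUE, r)$annual_kill
      n <- min(200L, length(k))
      if (sum(k) > 0) sum(k[seq_len(n)]) / sum(k) else NA_real_
    }, numeric(1))
    mean(f, na.rm = TRUE)
  }
  a2 <- (1 - conf) / 2
  list(percent = pct(ka, kb),
       ci = unname(stats::quantile(boot, c(a2, 1 - a2), na.rm = TRUE)),
       mean_a = mean(ka), mean_b = mean(kb),
       frac_first200_a = frac200(climate_a),
       frac_first200_b = frac200(climate_b))
}

## period mean of each indicator for one arm (mean over snapshots
## including year 0, then over replicates)
arm_period_means <- function(experiment, climate, disturbed) {
  reps <- experiment$design$replicates
  m <- vapply(seq_len(reps), function(r) {
    ind <- get_run(experiment, climate, disturbed, r)$indicators
    colMeans(ind[, BL_INDICATORS])
  }, numeric(length(BL_INDICATORS)))
  rowMeans(m)
}

#' Attribution of indicator responses to climate change and disturbance
#'
#' For each of the eight indicators, the period mean (all snapshots, all
#' replicates) of four arms is compared to the reference arm (baseline
#' climate, undisturbed): the effect of climate change alone
#' (`cc`-undisturbed), of disturbances alone (BC-disturbed) and of their
#' combination (`cc`-disturbed), each as a percent difference from the
#' reference mean.
#'
#' @param experiment a `bl_experiment` containing all four arms.
#' @param climate_cc the climate-change scenario to attribute.
#' @return data.frame: `indicator`, `ref_mean`, `effect_climate_pct`,
#'   `effect_disturbance_pct`, `effect_combined_pct`.
#' @export
attribution_table <- function(experiment, climate_cc = "HWC") {
  ref <- arm_period_means(experiment, "BC", FALSE)
  cc_only <- arm_period_means(experiment, climate_cc, FALSE)
  dist_only <- arm_period_means(experiment, "BC", TRUE)
  combined <- arm_period_means(experiment, climate_cc, TRUE)
  eff <- function(x) 100 * (x - ref) / ref
  data.frame(indicator = BL_INDICATORS, ref_mean = unname(ref),
             effect_climate_pct = unname(eff(cc_only)),
             effect_disturbance_pct = unname(eff(dist_only)),
             effect_combined_pct = unname(eff(combined)))
}
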