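## Annual Ips typographus outbreak dynamics on the landscape grid.
##
## The yearly cycle, executed in this fixed order by annual_beetle_step():
##   1. winter survival   — logistic in the winter minimum temperature;
##   2. brood amplification — P <- survival * (P + w * windthrown host
##      volume + background) * r^G, with G generations from the degree-day
##      sum (floor voltinism, PHENIPS-style defaults);
##   3. dispersal         — truncated exponential kernel, most beetles stay
##      within a few tens to hundreds of metres of the natal cell;
##   4. colonization/kill — attack succeeds where arriving pressure exceeds
##      the drought-modulated tree defence; killed volume is linear in the
##      pressure surplus and capped by the standing host volume;
##   5. seeding           — next year's pressure is kappa x killed volume.
##
## Pressure is a dimensionless brood-unit index; only its ratio to defence
## matters. The only stochastic element is attack success within a narrow
## margin around the defence threshold (plus the wind/regeneration draws
## made elsewhere), so trajectories are reproducible given climate and seed.

#' Construct an empty beetle state
#' @param nrow,ncol grid dimensions.
#' @param background baseline immigration pressure (index/yr).
#' @return object of class `bl_beetles` with a `pressure` matrix.
#' @export
new_beetle_state <- function(nrow, ncol, background = 0.5) {
  structure(list(pressure = matrix(0, nrow, ncol), background = background),
            class = "bl_beetles")
}

#' Completed beetle generations from the annual degree-day sum
#'
#' Floor voltinism: `floor(dd_sum / dd_per_generation)`, clamped to
#' `[0, max_generations]`; non-decreasing in `dd_sum`.
#'
#' @param dd_sum degree days above the development threshold.
#' @param params list with `dd_per_generation` and `max_generations`
#'   (defaults 557 degree days, 3 generations).
#' @export
thermal_generations <- function(dd_sum, params = default_config()$beetle) {
  if (any(!is.finite(dd_sum)) || any(dd_sum < 0)) {
    stop("dd_sum must be finite and >= 0")
  }
  pmin(params$max_generations, pmax(0, floor(dd_sum / params$dd_per_generation)))
}

#' Winter survival fraction
#'
#' Logistic in the winter minimum temperature:
#' \eqn{1 / (1 + e^{-k (t - t_{50})})}; strictly increasing, bounded in
#' (0, 1). Colder winters kill a larger fraction of the overwintering
#' population.
#'
#' @param t_min_winter_c winter minimum temperature, degC.
#' @param params list with `winter_t50` (degC) and `winter_slope` (1/degC).
#' @export
winter_survival <- function(t_min_winter_c, params = default_config()$beetle) {
  if (any(!is.finite(t_min_winter_c))) stop("non-finite winter temperature")
  stats::plogis(params$winter_slope * (t_min_winter_c - params$winter_t50))
}

#' Dispersal kernel matrix
#'
#' Stay-probability `p0` at the natal cell; the remaining mass distributed
#' over the truncation square proportional to \eqn{e^{-d/L}} of the
#' cell-centre distance. The kernel sums to 1, so total pressure is
#' conserved except for mass leaving the landscape edge.
#'
#' @param params beetle parameter list (`kernel_p0`, `kernel_length_m`,
#'   `kernel_radius_cells`).
#' @param cell_size_m cell edge length, m.
#' @keywords internal
dispersal_kernel <- function(params, cell_size_m = 100) {
  if (params$kernel_p0 < 0 || params$kernel_p0 > 1 ||
      params$kernel_length_m <= 0 || params$kernel_radius_cells < 1) {
    config_error("invalid dispersal kernel parameters")
  }
  r <- as.integer(params$kernel_radius_cells)
  d <- cell_size_m * sqrt(outer((-r:r)^2, (-r:r)^2, "+"))
  k <- exp(-d / params$kernel_length_m)
  k[r + 1, r + 1] <- 0
  k <- k / sum(k) * (1 - params$kernel_p0)
  k[r + 1, r + 1] <- params$kernel_p0
  k
}

#' Redistribute beetle pressure by dispersal
#'
#' @param pressure pressure matrix.
#' @param params beetle parameter list.
#' @param cell_size_m cell edge length, m.
#' @return pressure matrix of the same dimension.
#' @export
disperse_pressure <- function(pressure, params = default_config()$beetle,
                              cell_size_m = 100) {
  conv2d(pressure, dispersal_kernel(params, cell_size_m))
}

#' Host colonization and tree kill for one year
#'
#' Per cell, defence \eqn{D = d_0 \times \mathrm{host~BA} \times
#' \mathrm{drought~index}} (drought weakens defence). Attack succeeds where
#' arriving pressure \eqn{A > D} (stochastic only within a narrow margin
#' around the threshold); killed volume is
#' \eqn{\min(\mathrm{host~volume},\; c_{kill} (A - D))}, removed from the
#' live host cohorts and logged. Cells without host are never killed.
#'
#' @param state a `bl_landscape`.
#' @param pressure pressure matrix (post-dispersal).
#' @param climate one climate year.
#' @param config configuration list.
#' @return list with `state`, `records` (data.frame `year`, `cell`,
#'   `agent`, `volume_m3_ha`) and `kill_grid` (matrix of killed volume).
#' @export
colonize_and_kill <- function(state, pressure, climate,
                              config = default_config()) {
  b <- config$beetle
  host <- host_layers(state, b$host_dbh_cm, config$vegetation$form_factor)
  A <- as.vector(pressure)
  D <- b$defence_d0 * as.vector(host$basal_area) * climate$drought_index
  hv <- as.vector(host$volume)

  success <- A > D
  margin <- A > 0 & abs(A - D) <= b$attack_margin * pmax(D, 1)
  if (any(margin)) {
    success[margin] <- stats::runif(sum(margin)) < 0.5
  }
  kill <- pmin(hv, pmax(0, b$c_kill * (A - D)))
  kill[!success | hv <= 0] <- 0

  records <- data.frame(year = integer(), cell = integer(),
                        agent = character(), volume_m3_ha = numeric())
  if (any(kill > 0)) {
    frac <- numeric(length(kill))
    frac[kill > 0] <- kill[kill > 0] / hv[kill > 0]
    co <- state$cohorts
    is_host <- co$species == 1L & co$dbh > b$host_dbh_cm
    hit <- is_host & frac[co$cell] > 0
    co$stems[hit] <- co$stems[hit] * (1 - frac[co$cell[hit]])
    state$cohorts <- co[co$stems >= 1 | !hit, , drop = FALSE]
    idx <- which(kill > 0)
    records <- data.frame(year = state$year, cell = idx, agent = "beetle",
                          volume_m3_ha = kill[idx])
  }
  list(state = state,
       records = records,
       kill_grid = matrix(kill, state$nrow, state$ncol))
}

#' Advance the beetle population by one year
#'
#' Executes winter survival, windthrow-fuelled brood amplification over the
#' thermal generations, dispersal, colonization/kill, and seeding of next
#' year's pressure from killed volume, in that fixed order.
#'
#' @param state a `bl_landscape`.
#' @param climate one climate year.
#' @param wind_events data.frame of this year's wind events
#'   (from [apply_wind()]); may be empty.
#' @param beetles a `bl_beetles` state.
#' @param config configuration list.
#' @return list with `beetles` (next-year state), `state` (post-kill
#'   landscape) and `records` (kill log).
#' @export
annual_beetle_step <- function(state, climate, wind_events, beetles,
                               config = default_config()) {
  b <- config$beetle
  ncell <- state$nrow * state$ncol
  windvol <- matrix(0, state$nrow, state$ncol)
  if (!is.null(wind_events) && nrow(wind_events)) {
    windvol[wind_events$cell] <- wind_events$downed_host_volume_m3_ha
  }
  s <- winter_survival(climate$t_min_winter_c, b)
  G <- thermal_generations(climate$dd_sum, b)
  P <- s * (beetles$pressure + b$wind_coupling * windvol + beetles$background) *
    b$r_generation^G
  P <- disperse_pressure(P, b, state$cell_size_m)
  res <- colonize_and_kill(state, P, climate, config)
  beetles$pressure <- b$kappa * res$kill_grid
  list(beetles = beetles, state = res$state, records = res$records)
}
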