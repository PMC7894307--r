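## Annual vegetation dynamics: growth, background + senescence mortality,
## self-thinning at a basal-area cap, and gap regeneration fed by the
## 8-cell neighbourhood seed supply. This is the minimal cohort-based
## stand-in for a full individual-based forest landscape model: only the
## coupling between disturbance, structure and composition is represented.

#' Species temperature response
#'
#' Gaussian niche on mean annual temperature,
#' \eqn{\exp(-((T - T_{opt})/w)^2)}. Spruce has a cooler optimum than
#' beech/fir/other, so sustained warming shifts competition away from the
#' beetle's host.
#'
#' @param t_mean_c degC; `species` integer codes; `veg` vegetation params.
#' @keywords internal
temp_response <- function(t_mean_c, species, veg) {
  exp(-((t_mean_c - veg$temp_opt[species]) / veg$temp_width[species])^2)
}

#' Advance the vegetation by one year
#'
#' Order of operations: diameter/height growth (modulated by species
#' temperature response, drought index, site fertility and stand density),
#' background + senescence mortality, self-thinning to the basal-area cap,
#' then regeneration in cells below the canopy-closure threshold with
#' species drawn proportional to neighbourhood seed supply times climate
#' suitability. The year stamp increments by exactly 1. Uses the current
#' RNG stream (the scenario engine keeps vegetation on its own stream).
#'
#' @param state a `bl_landscape`.
#' @param climate one row of a `bl_climate` series (list or 1-row df).
#' @param config configuration list.
#' @return the updated `bl_landscape`.
#' @export
annual_vegetation_step <- function(state, climate, config = default_config()) {
  veg <- config$vegetation
  if (!all(is.finite(c(climate$t_mean_c, climate$precip_mm,
                       climate$drought_index)))) {
    stop("non-finite climate values")
  }
  co <- state$cohorts
  ncell <- state$nrow * state$ncol

  if (nrow(co)) {
    ba <- cohort_basal_area(co)
    ba_cell <- cell_aggregate(state, ba)

    ## growth
    tr <- temp_response(climate$t_mean_c, co$species, veg)
    dens <- pmax(0, 1 - ba_cell[co$cell] / veg$ba_cap)
    inc <- veg$growth_dbh[co$species] * tr * climate$drought_index *
      state$fertility[co$cell] * dens
    h_old <- allometric_height(co$dbh, co$species, veg)
    co$dbh <- co$dbh + inc
    co$height <- pmin(60, co$height +
                        (allometric_height(co$dbh, co$species, veg) - h_old))
    co$age <- co$age + 1

    ## mortality
    m <- pmin(0.3, veg$mortality +
                veg$mortality_senescence * (co$age / veg$age_ref)^3)
    co$stems <- co$stems * (1 - m)
    co <- co[co$stems >= 1, , drop = FALSE]

    ## self-thinning to the cap
    if (nrow(co)) {
      state$cohorts <- co
      ba_cell <- cell_aggregate(state, cohort_basal_area(co))
      over <- ba_cell > veg$ba_cap
      if (any(over)) {
        scale <- rep(1, ncell)
        scale[over] <- veg$ba_cap / ba_cell[over]
        co$stems <- co$stems * scale[co$cell]
      }
    }
  }
  state$cohorts <- co

  ## regeneration
  ba_cell <- cell_aggregate(state, cohort_basal_area(co))
  n_coh <- tabulate(co$cell, nbins = ncell)
  open <- ba_cell < veg$regen_ba_threshold & n_coh < veg$max_cohorts
  recruit <- which(open)
  if (length(recruit)) {
    recruit <- recruit[stats::runif(length(recruit)) < veg$regen_prob]
  }
  if (length(recruit)) {
    sp_ba <- species_basal_area(state)
    suit <- temp_response(climate$t_mean_c, seq_along(BL_SPECIES), veg)
    w <- matrix(0, length(recruit), length(BL_SPECIES))
    for (s in seq_along(BL_SPECIES)) {
      nbr <- neighbour_sum(matrix(sp_ba[, s], state$nrow, state$ncol),
                           include_self = TRUE)
      w[, s] <- (as.vector(nbr)[recruit] + veg$seed_immigration) * suit[s]
    }
    cum <- t(apply(w, 1, cumsum))
    tot <- cum[, ncol(cum)]
    u <- stats::runif(length(recruit)) * tot
    sp_new <- max.col(cum >= u, ties.method = "first")
    ## recruits join an existing young cohort of the same species if one is
    ## present (even-aged recovery); otherwise they found a new cohort
    young <- which(co$dbh < veg$regen_merge_dbh)
    m <- match(paste(recruit, sp_new),
               paste(co$cell[young], co$species[young]))
    hit <- !is.na(m)
    if (any(hit)) {
      i <- young[m[hit]]
      w_old <- co$stems[i]
      w_new <- veg$regen_stems
      co$dbh[i] <- (co$dbh[i] * w_old + veg$regen_dbh * w_new) / (w_old + w_new)
      co$height[i] <- (co$height[i] * w_old +
                         allometric_height(veg$regen_dbh, co$species[i], veg) *
                         w_new) / (w_old + w_new)
      co$age[i] <- (co$age[i] * w_old + veg$regen_age * w_new) / (w_old + w_new)
      co$stems[i] <- w_old + w_new
    }
    recruit <- recruit[!hit]; sp_new <- sp_new[!hit]
    state$cohorts <- co
    if (length(recruit)) {
      h0 <- allometric_height(veg$regen_dbh, sp_new, veg)
      state$cohorts <- rbind(co, data.frame(
        cell = recruit, species = sp_new,
        stems = rep(veg$regen_stems, length(recruit)),
        dbh = rep(veg$regen_dbh, length(recruit)),
        height = h0, age = rep(veg$regen_age, length(recruit))))
    }
  }
  state$year <- state$year + 1L
  state
}

#' Apply windthrow for one year
#'
#' A storm occurs with annual probability `p_event` (stationary: no trend
#' with the climate scenario). A storm downs a Beta-distributed fraction of
#' the stems of every cohort in the affected cells; the downed volume of
#' host spruce (dbh above the host threshold) is recorded per cell because
#' fresh downed spruce fuels beetle population growth the following spring.
#' Uses the current RNG stream.
#'
#' @param state a `bl_landscape`.
#' @param climate one climate year (unused by design: wind is
#'   climate-stationary; kept for interface symmetry).
#' @param config configuration list.
#' @return list with elements `state` and `events` (data.frame `year`,
#'   `cell`, `severity`, `downed_host_volume_m3_ha`,
#'   `downed_total_volume_m3_ha`).
#' @export
apply_wind <- function(state, climate, config = default_config()) {
  w <- config$wind
  empty <- data.frame(year = integer(), cell = integer(), severity = numeric(),
                      downed_host_volume_m3_ha = numeric(),
                      downed_total_volume_m3_ha = numeric())
  if (w$p_event <= 0 || stats::runif(1) >= w$p_event) {
    return(list(state = state, events = empty))
  }
  ncell <- state$nrow * state$ncol
  n_hit <- min(ncell, 1L + stats::rpois(1, max(0, w$mean_cells - 1)))
  cells <- sample.int(ncell, n_hit)
  sev <- stats::rbeta(n_hit, w$severity_shape1, w$severity_shape2)

  host <- host_layers(state, config$beetle$host_dbh_cm,
                      config$vegetation$form_factor)
  co <- state$cohorts
  vol <- cohort_volume(co, config$vegetation$form_factor)
  tot_cell <- cell_aggregate(state, vol)

  sev_cell <- numeric(ncell)
  sev_cell[cells] <- sev
  hit <- co$cell %in% cells
  co$stems[hit] <- co$stems[hit] * (1 - sev_cell[co$cell[hit]])
  state$cohorts <- co[co$stems >= 1, , drop = FALSE]

  events <- data.frame(year = state$year, cell = cells, severity = sev,
                       downed_host_volume_m3_ha = sev * as.vector(host$volume)[cells],
                       downed_total_volume_m3_ha = sev * tot_cell[cells])
  list(state = state, events = events)
}
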