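## Climate scenarios: annual series of temperature / precipitation /
## degree-day / drought descriptors. A synthetic "historical" reference
## block is resampled with replacement to build the baseline scenario (BC);
## the change scenarios (MC/HC/HWC) add a linear warming ramp over the
## first `ramp_years` years, then stay stationary at the endpoint delta.

BL_SCENARIOS <- c("BC", "MC", "HC", "HWC")

#' Degree-day sum above a development threshold
#'
#' The synthetic world has no daily weather, so the annual cycle is
#' approximated by a sinusoid around the annual mean:
#' \eqn{T(d) = \bar T + A \cos(2\pi d / 365)} and the degree-day sum is
#' \eqn{\sum_d \max(0, T(d) - thr)}.
#'
#' @param t_mean_c annual mean temperature(s), degC.
#' @param amplitude seasonal amplitude, degC.
#' @param threshold lower development threshold, degC.
#' @return degree-day sum(s), degC days.
#' @export
degree_day_sum <- function(t_mean_c, amplitude = 9, threshold = 8.3) {
  d <- seq_len(365)
  cyc <- amplitude * cos(2 * pi * (d - 1) / 365)
  vapply(t_mean_c, function(tm) sum(pmax(0, tm + cyc - threshold)), numeric(1))
}

#' Drought index from annual precipitation and temperature
#'
#' \eqn{\min(1, P / W(\bar T))} with water demand linear in temperature,
#' so warmer years are drier all else equal. 1 = no drought stress.
#'
#' @param precip_mm annual precipitation, mm.
#' @param t_mean_c annual mean temperature, degC.
#' @param demand_base,demand_per_degc demand intercept (mm) and slope
#'   (mm/degC).
#' @export
drought_index <- function(precip_mm, t_mean_c, demand_base = 500,
                          demand_per_degc = 100) {
  demand <- pmax(1, demand_base + demand_per_degc * t_mean_c)
  pmin(1, pmax(0, precip_mm / demand))
}

climate_from_core <- function(t_mean, t_min_winter, precip, cc) {
  data.frame(year = seq_along(t_mean),
             t_mean_c = t_mean,
             t_min_winter_c = pmin(t_min_winter, t_mean),
             precip_mm = precip,
             dd_sum = degree_day_sum(t_mean, cc$seasonal_amplitude, cc$dd_threshold),
             drought_index = drought_index(precip, t_mean, cc$demand_base,
                                           cc$demand_per_degc))
}

#' Build a climate scenario
#'
#' Generates the synthetic reference block (interannual normal variability
#' around the configured landscape means), resamples it with replacement to
#' the requested horizon, and applies the scenario's warming ramp. Two
#' scenarios built with the same seed share all random draws, so HWC and HC
#' have identical temperatures and differ only by the precipitation factor.
#'
#' @param name one of `"BC"`, `"MC"`, `"HC"`, `"HWC"`.
#' @param horizon_yr length of the series, years.
#' @param seed integer seed.
#' @param config configuration list (section `climate` is used).
#' @return object of class `bl_climate`: a data.frame with columns `year`,
#'   `t_mean_c`, `t_min_winter_c`, `precip_mm`, `dd_sum`, `drought_index`
#'   and attribute `"name"`.
#' @export
make_climate_scenario <- function(name, horizon_yr, seed = 1L,
                                  config = default_config()) {
  cc <- config$climate
  if (!name %in% BL_SCENARIOS) {
    config_error(sprintf("unknown climate scenario '%s'", name))
  }
  if (horizon_yr < 1) config_error("horizon_yr must be >= 1")
  set.seed(seed)
  n_ref <- cc$n_ref_years
  ref_t <- stats::rnorm(n_ref, cc$t_mean, cc$t_sd)
  ref_p <- pmax(300, stats::rnorm(n_ref, cc$precip_mean, cc$precip_sd))
  ref_w <- stats::rnorm(n_ref, 0, cc$winter_sd)   # winter minimum anomaly
  idx <- sample.int(n_ref, horizon_yr, replace = TRUE)

  yr <- seq_len(horizon_yr)
  ramp <- pmin(1, yr / cc$ramp_years)
  dt <- cc$delta_t[[name]] * ramp
  pf <- 1 + (cc$precip_factor[[name]] - 1) * ramp

  t_mean <- ref_t[idx] + dt
  precip <- ref_p[idx] * pf
  t_min <- t_mean - cc$winter_offset + ref_w[idx]
  out <- climate_from_core(t_mean, t_min, precip, cc)
  attr(out, "name") <- name
  attr(out, "reference_t_mean") <- ref_t
  class(out) <- c("bl_climate", "data.frame")
  out
}

#' Extend a climate series by resampling a terminal window
#'
#' Years beyond the input series are drawn with replacement from the given
#' window of the input (the analogue of extending a transient scenario by
#' resampling its last decades); the input prefix is returned unchanged.
#'
#' @param years a `bl_climate` or climate data.frame.
#' @param horizon_yr requested total length; must be >= the input length.
#' @param resample_window integer index range inside the input series.
#' @param seed integer seed.
#' @export
extend_climate_series <- function(years, horizon_yr,
                                  resample_window = seq_len(nrow(years)),
                                  seed = 1L) {
  n <- nrow(years)
  if (horizon_yr < n) stop("horizon_yr must be >= the input series length")
  if (!length(resample_window) || min(resample_window) < 1 ||
      max(resample_window) > n) {
    stop("resample_window must be a non-empty index range inside the series")
  }
  if (horizon_yr == n) return(years)
  set.seed(seed)
  idx <- resample_window[sample.int(length(resample_window),
                                    horizon_yr - n, replace = TRUE)]
  out <- rbind(as.data.frame(years), as.data.frame(years)[idx, , drop = FALSE])
  out$year <- seq_len(horizon_yr)
  rownames(out) <- NULL
  attr(out, "name") <- attr(years, "name")
  class(out) <- class(years)
  out
}
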