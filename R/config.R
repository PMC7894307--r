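## Run configuration: nested list of named scalar parameters, one section
## per process group. Every parameter has a default; load_config() merges a
## YAML file over the defaults and rejects unknown keys.

#' Indicator column names
#'
#' The eight structural/compositional diversity indicators, in canonical
#' column order.
#' @export
BL_INDICATORS <- c("AlpHei", "AlpDbh", "CanCov", "RumInd",
                   "BetHei", "BetDbh", "ProSpr", "AggInd")

#' Default run configuration
#'
#' Returns the full nested parameter list. Units are given in the comments
#' of each entry below and echoed in the YAML written by [write_outputs()].
#'
#' The `desk` preset (50 x 50 cells, 300 years, 5 replicate pairs) is sized
#' for interactive analysis; the `paper` preset (120 x 120 cells, 600 years,
#' 20 replicate pairs) approximates the extent and design of a full
#' landscape study on a ~14,000 ha mountain forest.
#'
#' @param preset `"desk"` or `"paper"`.
#' @return nested named list with sections `landscape`, `climate`,
#'   `vegetation`, `wind`, `beetle`, `indicators`, `experiment`, `feedback`.
#' @export
default_config <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    landscape = list(
      nrow = 50L,                    # cells
      ncol = 50L,                    # cells
      cell_size_m = 100,             # m
      target_spruce_share = 60.5,    # % of total basal area
      ba_mean = 32,                  # m2/ha initial stand basal area
      ba_sd = 8,                     # m2/ha
      field_range_cells = 4,         # autocorrelation range of composition field
      elevation_effect = 1.0,        # logit shift of spruce share across the
                                     # elevation (row) gradient, high rows = high elevation
      fertility_min = 0.7,           # dimensionless site multiplier
      fertility_max = 1.3
    ),
    climate = list(
      n_ref_years = 36,              # length of the synthetic "historical" block
      t_mean = 6.0,                  # degC landscape mean annual temperature
      t_sd = 0.8,                    # degC interannual sd
      precip_mean = 1400,            # mm/yr
      precip_sd = 180,               # mm/yr
      winter_offset = 14,            # degC, t_mean minus mean winter minimum
      winter_sd = 1.5,               # degC interannual sd of winter minimum anomaly
      seasonal_amplitude = 9,        # degC amplitude of the sinusoidal annual cycle
      dd_threshold = 8.3,            # degC lower development threshold for degree days
      demand_base = 500,             # mm/yr water demand at 0 degC
      demand_per_degc = 100,         # mm/yr/degC slope of water demand
      ramp_years = 90,               # years of the linear warming ramp
      # scenario endpoint deltas (placeholders, configurable; the downscaled
      # scenario anomalies of a real application replace these)
      delta_t = c(BC = 0, MC = 2.0, HC = 4.5, HWC = 4.5),        # degC
      precip_factor = c(BC = 1, MC = 1, HC = 1, HWC = 1.10)      # multiplicative
    ),
    vegetation = list(
      species = c("spruce", "beech", "fir", "other"),
      growth_dbh = c(spruce = 0.60, beech = 0.55, fir = 0.55, other = 0.65), # cm/yr at optimum in the open
      temp_opt = c(spruce = 5.5, beech = 8.5, fir = 7.0, other = 9.0),       # degC optimum mean annual temperature
      temp_width = c(spruce = 6.0, beech = 5.0, fir = 4.5, other = 5.5),     # degC Gaussian niche width
      h_max = c(spruce = 45, beech = 40, fir = 48, other = 35),              # m asymptotic height
      h_curve = c(spruce = 0.035, beech = 0.04, fir = 0.033, other = 0.05),  # 1/cm allometry curvature
      form_factor = 0.5,             # stem volume = ff * basal area * height
      mortality = 0.012,             # 1/yr background mortality of stems
      mortality_senescence = 0.008,  # 1/yr additional at age_ref
      age_ref = 220,                 # yr senescence reference age
      ba_cap = 60,                   # m2/ha self-thinning cap
      regen_ba_threshold = 25,       # m2/ha canopy-closure threshold below which regeneration occurs
      regen_prob = 0.35,             # 1/yr establishment probability in open cells
      regen_stems = 400,             # stems/ha of a new seedling cohort
      regen_dbh = 1.5,               # cm
      regen_age = 5,                 # yr
      regen_merge_dbh = 10,          # cm; recruits join an existing young cohort
                                     # of the same species below this dbh
                                     # (even-aged post-disturbance recovery)
      seed_immigration = 0.5,        # m2/ha-equivalent background seed supply per species
      max_cohorts = 8                # per cell
    ),
    wind = list(
      p_event = 0.4,                 # 1/yr probability of a storm event
      mean_cells = 8,                # mean number of cells hit per event
      severity_shape1 = 2,           # Beta distribution of the stem fraction downed
      severity_shape2 = 2
    ),
    beetle = list(
      dd_per_generation = 557,       # degree days per completed generation
      max_generations = 3,
      winter_t50 = -14,              # degC winter minimum at 50 % survival
      winter_slope = 0.35,           # 1/degC logistic slope
      r_generation = 2.2,            # per-generation multiplication factor
      wind_coupling = 0.5,           # pressure units per m3/ha of fresh downed host
      background = 3,                # pressure units/yr endemic immigration
      kernel_p0 = 0.5,               # probability of staying in the natal cell
      kernel_length_m = 150,         # e-folding distance of the dispersal kernel
      kernel_radius_cells = 3,       # truncation radius
      defence_d0 = 1.5,              # pressure units per m2/ha host basal area
      c_kill = 0.5,                  # m3/ha killed per pressure unit exceeding defence
      kappa = 0.7,                   # pressure units next year per m3/ha killed
      host_dbh_cm = 15,              # cm dbh above which spruce is a host
      attack_margin = 0.05           # relative width of the stochastic attack margin
    ),
    indicators = list(
      height_class_m = 4,            # m class width for height diversity
      dbh_class_cm = 4,              # cm class width for diameter diversity
      k_cov = 0.07,                  # 1/(m2/ha) Beer-Lambert canopy cover coefficient
      host_dbh_cm = 15,              # cm host threshold for the aggregation index
      aggind_min_cluster = 2,        # cells; minimum component size counted as contiguous
      beta_effective_numbers = TRUE  # beta on the effective-number (exp entropy) scale
    ),
    experiment = list(
      horizon_yr = 300L,             # yr
      indicator_step_yr = 50L,       # yr
      replicates = 5L,
      climates = c("BC", "MC", "HC", "HWC"),
      base_seed = 42L
    ),
    feedback = list(
      window_yr = 50L,               # yr aggregation window of the training table
      ntree = 500L,
      mtry = NULL,                   # default: floor(p/2), see fit_surrogate()
      n_boot = 500L                  # bootstrap replicates for CIs
    )
  )
  if (preset == "paper") {
    cfg$landscape$nrow <- 120L
    cfg$landscape$ncol <- 120L
    cfg$experiment$horizon_yr <- 600L
    cfg$experiment$replicates <- 20L
  }
  cfg
}

config_error <- function(msg) {
  stop(structure(class = c("bl_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

merge_config <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  if (!is.list(override)) config_error(sprintf("section '%s' must be a mapping", path))
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      config_error(sprintf("unknown configuration key '%s'", full))
    }
    if (is.list(defaults[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], override[[key]], full)
    } else {
      val <- override[[key]]
      if (is.list(val)) val <- unlist(val)
      if (is.numeric(defaults[[key]]) && !is.numeric(val)) {
        config_error(sprintf("key '%s' must be numeric", full))
      }
      if (!is.null(names(defaults[[key]])) && !is.null(names(val))) {
        tmp <- defaults[[key]]
        bad <- setdiff(names(val), names(tmp))
        if (length(bad)) config_error(sprintf("unknown entry '%s' in key '%s'", bad[1], full))
        tmp[names(val)] <- val
        val <- tmp
      }
      defaults[[key]] <- val
    }
  }
  defaults
}

#' Load a run configuration from a YAML file
#'
#' Missing keys fall back to [default_config()]; unknown keys raise an error
#' naming the offending key. An empty file yields the full defaults.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @param preset preset passed to [default_config()].
#' @return a configuration list with attribute `"hash"` (MD5 of the merged,
#'   canonicalised configuration) used to tag outputs.
#' @export
load_config <- function(path = NULL, preset = "desk") {
  override <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) config_error(sprintf("config file '%s' not found", path))
    override <- yaml::read_yaml(path)
  }
  if (!is.null(override$preset)) {
    preset <- override$preset
    override$preset <- NULL
    if (!preset %in% c("desk", "paper")) config_error("preset must be 'desk' or 'paper'")
  }
  cfg <- default_config(preset)
  cfg <- merge_config(cfg, override)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' @rdname load_config
#' @param config a configuration list.
#' @export
config_hash <- function(config) {
  attr(config, "hash") <- NULL
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(config, control = "all"), tf)
  unname(tools::md5sum(tf))
}
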