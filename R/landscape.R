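## LandscapeState: a grid of 1-ha cells, each holding a list of tree
## cohorts. Cohorts are stored in one flat data.frame (column `cell` is the
## column-major cell index) so that all annual dynamics can be vectorised.

#' Species set
#'
#' Integer cohort species codes: 1 = Norway spruce (the bark beetle host),
#' 2 = European beech, 3 = silver fir, 4 = other (minor species pooled).
#' @export
BL_SPECIES <- c("spruce", "beech", "fir", "other")

#' Construct a landscape state
#'
#' @param nrow,ncol grid dimensions in cells (each cell is 1 ha, 100 m).
#' @param cohorts data.frame with columns `cell` (column-major index),
#'   `species` (integer code into [BL_SPECIES]), `stems` (stems/ha),
#'   `dbh` (cm), `height` (m), `age` (yr).
#' @param fertility numeric vector of per-cell site multipliers in
#'   \eqn{[0.5, 1.5]}.
#' @param year simulation year stamp.
#' @param cell_size_m cell edge length, m.
#' @return object of class `bl_landscape`.
#' @export
new_landscape <- function(nrow, ncol, cohorts, fertility, year = 0L,
                          cell_size_m = 100) {
  stopifnot(nrow >= 2, ncol >= 2, length(fertility) == nrow * ncol)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cell_size_m = cell_size_m, year = as.integer(year),
                 fertility = fertility, cohorts = cohorts),
            class = "bl_landscape")
}

#' @export
print.bl_landscape <- function(x, ...) {
  ba <- sum(cohort_basal_area(x$cohorts)) / (x$nrow * x$ncol)
  cat(sprintf("<bl_landscape> %d x %d cells (%.0f ha), year %d\n",
              x$nrow, x$ncol, x$nrow * x$ncol * (x$cell_size_m / 100)^2, x$year))
  cat(sprintf("  %d cohorts, mean basal area %.1f m2/ha, spruce share %.1f %%\n",
              nrow(x$cohorts), ba, spruce_proportion_safe(x)))
  invisible(x)
}

spruce_proportion_safe <- function(state) {
  ba <- cohort_basal_area(state$cohorts)
  tot <- sum(ba)
  if (tot <= 0) return(NA_real_)
  100 * sum(ba[state$cohorts$species == 1L]) / tot
}

#' Per-cohort basal area (m2/ha)
#' @param cohorts cohort data.frame.
#' @export
cohort_basal_area <- function(cohorts) {
  cohorts$stems * pi * (cohorts$dbh / 200)^2
}

#' Per-cohort stem volume (m3/ha), V = form factor x basal area x height
#' @param cohorts cohort data.frame.
#' @param form_factor dimensionless, default 0.5.
#' @export
cohort_volume <- function(cohorts, form_factor = 0.5) {
  form_factor * cohort_basal_area(cohorts) * cohorts$height
}

## Aggregate a per-cohort quantity to a full-length per-cell vector.
cell_aggregate <- function(state, values, fun = "sum") {
  out <- numeric(state$nrow * state$ncol)
  if (length(values)) {
    agg <- switch(fun,
                  sum = rowsum(values, state$cohorts$cell),
                  max = tapply(values, state$cohorts$cell, max))
    out[as.integer(rownames(agg))] <- as.numeric(agg)
  }
  out
}

#' Per-cell basal area, as a matrix (m2/ha)
#' @param state a `bl_landscape`.
#' @export
cell_basal_area <- function(state) {
  matrix(cell_aggregate(state, cohort_basal_area(state$cohorts)),
         state$nrow, state$ncol)
}

#' Per-cell species basal area (m2/ha)
#' @param state a `bl_landscape`.
#' @return ncells x 4 matrix, one column per species.
#' @keywords internal
species_basal_area <- function(state) {
  ba <- cohort_basal_area(state$cohorts)
  out <- matrix(0, state$nrow * state$ncol, length(BL_SPECIES))
  if (nrow(state$cohorts)) {
    for (s in seq_along(BL_SPECIES)) {
      sel <- state$cohorts$species == s
      if (any(sel)) {
        agg <- rowsum(ba[sel], state$cohorts$cell[sel])
        out[as.integer(rownames(agg)), s] <- as.numeric(agg)
      }
    }
  }
  out
}

#' Per-cell host quantities
#'
#' Host trees are spruce cohorts with mean dbh above the host threshold
#' (default 15 cm); these are the trees bark beetles can colonise.
#'
#' @param state a `bl_landscape`.
#' @param host_dbh_cm host diameter threshold, cm.
#' @param form_factor volume form factor.
#' @return list with matrices `volume` (m3/ha) and `basal_area` (m2/ha).
#' @export
host_layers <- function(state, host_dbh_cm = 15, form_factor = 0.5) {
  co <- state$cohorts
  sel <- co$species == 1L & co$dbh > host_dbh_cm
  sub <- co[sel, , drop = FALSE]
  vol <- ba <- numeric(state$nrow * state$ncol)
  if (nrow(sub)) {
    v <- rowsum(cohort_volume(sub, form_factor), sub$cell)
    b <- rowsum(cohort_basal_area(sub), sub$cell)
    vol[as.integer(rownames(v))] <- as.numeric(v)
    ba[as.integer(rownames(b))] <- as.numeric(b)
  }
  list(volume = matrix(vol, state$nrow, state$ncol),
       basal_area = matrix(ba, state$nrow, state$ncol))
}

#' Per-cell top height (m): tallest cohort, 0 for empty cells
#' @param state a `bl_landscape`.
#' @export
top_height <- function(state) {
  matrix(cell_aggregate(state, state$cohorts$height, "max"),
         state$nrow, state$ncol)
}

#' Height-diameter allometry
#'
#' Monotone saturating curve \eqn{h = 1.3 + (h_{max}-1.3)(1-e^{-c\,dbh})}.
#'
#' @param dbh cm; `species` integer codes; `veg` vegetation parameter list.
#' @keywords internal
allometric_height <- function(dbh, species, veg) {
  hmax <- veg$h_max[species]
  hc <- veg$h_curve[species]
  pmin(60, 1.3 + (hmax - 1.3) * (1 - exp(-hc * dbh)))
}

#' Validate landscape invariants
#'
#' Checks finiteness, non-negative pools, the height bound and the
#' basal-area cap. Called by the scenario engine after every annual step.
#'
#' @param state a `bl_landscape`.
#' @param ba_cap self-thinning cap, m2/ha (checked with 5 % headroom).
#' @return `TRUE` invisibly; errors with a diagnostic naming the cell.
#' @export
validate_landscape <- function(state, ba_cap = 80) {
  co <- state$cohorts
  ok <- is.finite(co$stems) & co$stems >= 0 & is.finite(co$dbh) & co$dbh > 0 &
    is.finite(co$height) & co$height > 0 & co$height <= 60 & co$age >= 0
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("invalid cohort in cell %d at year %d", co$cell[bad], state$year))
  }
  ba <- cell_aggregate(state, cohort_basal_area(co))
  if (any(ba > ba_cap + 1e-6)) {
    bad <- which.max(ba)
    stop(sprintf("basal area %.1f above cap in cell %d at year %d",
                 ba[bad], bad, state$year))
  }
  invisible(TRUE)
}

#' Generate a synthetic initial landscape
#'
#' Builds a mixed mountain-forest landscape on a regular 100-m grid with a
#' prescribed spruce share of total basal area, a spatially autocorrelated
#' composition pattern (smoothed Gaussian random field on the logit of the
#' cell spruce fraction), and an elevation-like fertility/composition
#' gradient along the rows (high rows = high elevation: more spruce, lower
#' fertility). The realised spruce share matches the target closely because
#' the logit intercept is calibrated by root finding before cohorts are
#' drawn.
#'
#' @param config configuration list from [default_config()]/[load_config()].
#' @param seed integer seed; identical (config, seed) give bit-identical
#'   landscapes.
#' @return a `bl_landscape` at year 0.
#' @export
generate_initial_landscape <- function(config = default_config(), seed = 1L) {
  l <- config$landscape
  veg <- config$vegetation
  if (l$nrow < 2 || l$ncol < 2) config_error("grid must be at least 2 x 2 cells")
  if (l$target_spruce_share < 0 || l$target_spruce_share > 100) {
    config_error("target_spruce_share must be in [0, 100]")
  }
  set.seed(seed)
  nr <- as.integer(l$nrow); nc <- as.integer(l$ncol)
  ncell <- nr * nc
  elev <- matrix(rep((seq_len(nr) - 1) / (nr - 1), nc), nr, nc)  # 0 = valley, 1 = ridge

  fert <- l$fertility_max - (l$fertility_max - l$fertility_min) * elev +
    stats::rnorm(ncell, 0, 0.03)
  fert <- pmin(1.5, pmax(0.5, as.vector(fert)))

  ba_cell <- pmin(50, pmax(10, stats::rnorm(ncell, l$ba_mean, l$ba_sd)))

  target <- l$target_spruce_share / 100
  if (target <= 0) {
    p_spruce <- rep(0, ncell)
  } else if (target >= 1) {
    p_spruce <- rep(1, ncell)
  } else {
    z <- as.vector(smooth_field(nr, nc, l$field_range_cells))
    eta0 <- 1.2 * z + l$elevation_effect * (as.vector(elev) - 0.5) * 2
    share_at <- function(c0) {
      p <- stats::plogis(c0 + eta0)
      sum(p * ba_cell) / sum(ba_cell) - target
    }
    c0 <- stats::uniroot(share_at, c(-12, 12), tol = 1e-10)$root
    p_spruce <- stats::plogis(c0 + eta0)
  }

  ## cohort slots, fully vectorised over cells
  ba_sp <- p_spruce * ba_cell
  ba_ns <- ba_cell - ba_sp

  ## non-spruce split: beech at low, fir at mid, "other" mixed in lightly
  ev <- as.vector(elev)
  w_beech <- pmax(0.05, 1.2 * (1 - ev)) * stats::rgamma(ncell, 4, 4)
  w_fir <- 0.8 * stats::rgamma(ncell, 4, 4)
  w_other <- (0.15 + 0.3 * ev) * stats::rgamma(ncell, 4, 4)
  w_tot <- w_beech + w_fir + w_other

  slots <- list()
  add_slot <- function(mask, species, ba, dbh_mean, dbh_sd, dbh_lo, dbh_hi) {
    keep <- mask & ba >= 0.5
    if (!any(keep)) return(invisible(NULL))
    n <- sum(keep)
    dbh <- pmin(dbh_hi, pmax(dbh_lo, stats::rnorm(n, dbh_mean, dbh_sd)))
    height <- allometric_height(dbh, rep(species, n), veg) *
      stats::runif(n, 0.92, 1.02)
    slots[[length(slots) + 1]] <<- data.frame(
      cell = which(keep), species = rep(species, n),
      stems = ba[keep] / (pi * (dbh / 200)^2),
      dbh = dbh, height = pmax(1.4, height),
      age = pmax(5, round(dbh * 1.8 + stats::rnorm(n, 0, 25))))
    invisible(NULL)
  }

  has_under <- stats::runif(ncell) < 0.5            # spruce understorey layer
  f_under <- ifelse(has_under, stats::runif(ncell, 0.1, 0.3), 0)
  add_slot(ba_sp > 0, 1L, ba_sp * (1 - f_under), 35, 6, 20, 60)
  add_slot(ba_sp > 0 & has_under, 1L, ba_sp * f_under, 11, 3, 4, 15)
  add_slot(ba_ns > 0, 2L, ba_ns * w_beech / w_tot, 30, 7, 8, 60)
  add_slot(ba_ns > 0, 3L, ba_ns * w_fir / w_tot, 32, 7, 8, 65)
  add_slot(ba_ns > 0, 4L, ba_ns * w_other / w_tot, 22, 6, 6, 45)

  cohorts <- if (length(slots)) do.call(rbind, slots) else
    data.frame(cell = integer(), species = integer(), stems = numeric(),
               dbh = numeric(), height = numeric(), age = numeric())
  cohorts <- cohorts[order(cohorts$cell, cohorts$species, cohorts$dbh), ]
  rownames(cohorts) <- NULL
  new_landscape(nr, nc, cohorts, fert, year = 0L, cell_size_m = l$cell_size_m)
}

#' Landscape snapshot as a long-format data.frame
#'
#' One row per cohort with grid coordinates and species names; the format
#' written to CSV by [write_outputs()] and accepted by
#' [landscape_from_df()].
#'
#' @param state a `bl_landscape`.
#' @export
landscape_to_df <- function(state) {
  co <- state$cohorts
  data.frame(row = ((co$cell - 1L) %% state$nrow) + 1L,
             col = ((co$cell - 1L) %/% state$nrow) + 1L,
             species = BL_SPECIES[co$species],
             stems_per_ha = co$stems, mean_dbh_cm = co$dbh,
             mean_height_m = co$height, age_yr = co$age)
}

#' Rebuild a landscape from a long-format data.frame
#'
#' @param df data.frame in the layout of [landscape_to_df()].
#' @param nrow,ncol grid dimensions (default: maxima of the coordinates).
#' @param fertility optional per-cell fertility vector (default 1).
#' @param year year stamp.
#' @export
landscape_from_df <- function(df, nrow = max(df$row), ncol = max(df$col),
                              fertility = NULL, year = 0L) {
  if (is.null(fertility)) fertility <- rep(1, nrow * ncol)
  cohorts <- data.frame(cell = (df$col - 1L) * nrow + df$row,
                        species = match(df$species, BL_SPECIES),
                        stems = df$stems_per_ha, dbh = df$mean_dbh_cm,
                        height = df$mean_height_m, age = df$age_yr)
  new_landscape(nrow, ncol, cohorts, fertility, year = year)
}
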