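## Random-forest counterfactual feedback quantification.
##
## A surrogate model is trained on the disturbed runs only, predicting the
## beetle-killed volume of each 50-year window from the eight diversity
## indicators at window start plus window climate. Feeding the model the
## covariates of the matched undisturbed run (same climate, replicate and
## window; climate columns always factual) isolates the effect of
## disturbance-mediated vegetation change on subsequent beetle activity:
## a negative percent effect means the disturbed landscape supports less
## future disturbance than the undisturbed one would, i.e. a dampening
## (self-regulating) feedback.

BL_SWAP_SETS <- list(
  all = c(BL_INDICATORS),
  composition_only = c("ProSpr", "AggInd"),
  structure_only = c("AlpHei", "AlpDbh", "CanCov", "RumInd", "BetHei", "BetDbh"))

BL_CLIMATE_PREDICTORS <- c("t_mean_window_c", "precip_window_mm")

#' Build the surrogate training table
#'
#' One row per (climate, replicate, window) of the disturbed runs:
#' response = beetle-killed volume summed over the window (m3/ha);
#' predictors = the eight indicators at the window-start snapshot plus the
#' window-mean temperature and window-sum precipitation.
#'
#' @param experiment a `bl_experiment` with disturbed arms.
#' @param window_yr window length, years; must equal the experiment's
#'   indicator snapshot step so windows align with snapshots.
#' @param disturbed build from the disturbed (`TRUE`, default, used for
#'   training) or undisturbed (`FALSE`, used for counterfactual covariates)
#'   arms.
#' @return data.frame with key columns `climate`, `replicate`, `window`,
#'   response `kill_m3_ha` and the ten predictors.
#' @export
build_training_table <- function(experiment, window_yr = 50,
                                 disturbed = TRUE) {
  des <- experiment$design
  if (window_yr != des$indicator_step_yr) {
    stop("window_yr must equal the experiment's indicator_step_yr")
  }
  n_win <- des$horizon_yr %/% window_yr
  rows <- list()
  for (cl in des$climates) {
    for (r in seq_len(des$replicates)) {
      run <- get_run(experiment, cl, disturbed, r)
      ind <- run$indicators
      for (w in seq_len(n_win)) {
        yrs <- ((w - 1) * window_yr + 1):(w * window_yr)
        start_year <- (w - 1) * window_yr
        snap <- ind[ind$year == start_year, BL_INDICATORS]
        rows[[length(rows) + 1]] <- cbind(
          data.frame(climate = cl, replicate = r, window = w,
                     kill_m3_ha = sum(run$annual_kill[yrs])),
          snap,
          data.frame(t_mean_window_c = mean(run$climate$t_mean_c[yrs]),
                     precip_window_mm = sum(run$climate$precip_mm[yrs])))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(!anyNA(out))
  out
}

#' Fit the random-forest surrogate
#'
#' Bagged regression trees ([randomForest::randomForest]) on the training
#' table; refitting with the same seed reproduces predictions exactly.
#'
#' @param table training table from [build_training_table()].
#' @param ntree number of trees.
#' @param mtry predictors tried per split. Default `floor(p/2)`: with only
#'   ten predictors whose strongest is climate, the conventional p/3
#'   subsampling lets correlated structure indicators absorb the climate
#'   signal and inflates counterfactual predictions under baseline climate;
#'   half the features keeps climate available at most splits.
#' @param seed integer seed.
#' @return object of class `bl_surrogate`: list with the fitted `forest`,
#'   `features`, `oob_r2` (variance explained on out-of-bag samples) and
#'   `seed`.
#' @export
fit_surrogate <- function(table, ntree = 500, mtry = NULL, seed = 1L) {
  features <- c(BL_INDICATORS, BL_CLIMATE_PREDICTORS)
  x <- table[, features]
  y <- table$kill_m3_ha
  if (nrow(x) < 50) stop("need at least 50 training rows")
  if (stats::var(y) == 0) {
    warning("degenerate fit: constant response")
    return(structure(list(forest = NULL, constant = y[1], features = features,
                          oob_r2 = NA_real_, seed = seed),
                     class = "bl_surrogate"))
  }
  if (is.null(mtry)) mtry <- max(1, floor(length(features) / 2))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry)
  structure(list(forest = rf, constant = NULL, features = features,
                 oob_r2 = rf$rsq[length(rf$rsq)], seed = seed),
            class = "bl_surrogate")
}

#' @export
print.bl_surrogate <- function(x, ...) {
  cat(sprintf("<bl_surrogate> %d features, OOB R2 = %.3f\n",
              length(x$features), x$oob_r2))
  invisible(x)
}

#' Predict from the surrogate
#' @param object a `bl_surrogate`; `newdata` a data.frame with the feature
#'   columns.
#' @param ... unused.
#' @param newdata data.frame.
#' @export
predict.bl_surrogate <- function(object, newdata, ...) {
  if (is.null(object$forest)) {
    return(rep(object$constant, nrow(newdata)))
  }
  as.numeric(stats::predict(object$forest, newdata[, object$features]))
}

## factual/counterfactual covariate pair for one climate scenario
counterfactual_tables <- function(experiment, swap_set, climate,
                                  window_yr = 50) {
  swap_cols <- BL_SWAP_SETS[[swap_set]]
  if (is.null(swap_cols)) stop("swap_set must be one of: ",
                               paste(names(BL_SWAP_SETS), collapse = ", "))
  fact <- build_training_table(experiment, window_yr, disturbed = TRUE)
  cf_src <- build_training_table(experiment, window_yr, disturbed = FALSE)
  fact <- fact[fact$climate == climate, ]
  cf_src <- cf_src[cf_src$climate == climate, ]
  key <- function(d) paste(d$climate, d$replicate, d$window)
  m <- match(key(fact), key(cf_src))
  if (anyNA(m)) stop("unmatched disturbed/undisturbed arms")
  cf <- fact
  cf[, swap_cols] <- cf_src[m, swap_cols]
  ## climate columns stay factual by construction
  stopifnot(identical(cf[, BL_CLIMATE_PREDICTORS], fact[, BL_CLIMATE_PREDICTORS]))
  list(factual = fact, counterfactual = cf)
}

#' Counterfactual feedback estimate
#'
#' Predicts the window kill sums under (a) the factual disturbed covariates
#' and (b) covariates with the swap-set columns replaced by the matched
#' undisturbed run's values, and reports
#' \eqn{100 (\Sigma \hat y_a - \Sigma \hat y_b) / \Sigma \hat y_b}
#' (negative = dampening feedback) with a bootstrap CI over replicates.
#'
#' @param model a `bl_surrogate`.
#' @param experiment a `bl_experiment` with matched arms.
#' @param swap_set `"all"`, `"composition_only"` or `"structure_only"`.
#' @param climate scenario to evaluate.
#' @param window_yr window length (the experiment's indicator step).
#' @param n_boot bootstrap replicates; `conf` confidence level.
#' @return object of class `bl_feedback`: list with `swap_set`, `climate`,
#'   `pred_disturbed_sum`, `pred_undisturbed_sum`, `percent_effect`, `ci`.
#' @export
counterfactual_feedback <- function(model, experiment, swap_set = "all",
                                    climate = "HC", window_yr = 50,
                                    n_boot = 500, conf = 0.95) {
  tabs <- counterfactual_tables(experiment, swap_set, climate, window_yr)
  ya <- predict(model, tabs$factual)
  yb <- predict(model, tabs$counterfactual)
  pct <- function(sa, sb) 100 * (sa - sb) / sb
  reps <- unique(tabs$factual$replicate)
  boot <- replicate(n_boot, {
    rs <- sample(reps, replace = TRUE)
    sel <- unlist(lapply(rs, function(r) which(tabs$factual$replicate == r)))
    pct(sum(ya[sel]), sum(yb[sel]))
  })
  a2 <- (1 - conf) / 2
  structure(list(swap_set = swap_set, climate = climate,
                 pred_disturbed_sum = sum(ya), pred_undisturbed_sum = sum(yb),
                 percent_effect = pct(sum(ya), sum(yb)),
                 ci = unname(stats::quantile(boot, c(a2, 1 - a2), na.rm = TRUE))),
            class = "bl_feedback")
}

#' @export
print.bl_feedback <- function(x, ...) {
  cat(sprintf("<bl_feedback> %s / %s: %.1f %% [%.1f, %.1f]\n", x$climate,
              x$swap_set, x$percent_effect, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Swap-set decomposition of the feedback
#'
#' Runs [counterfactual_feedback()] for all three swap sets (all
#' indicators, composition only = ProSpr + AggInd, structure only = the
#' six structural indicators) for each requested climate, from the same
#' fitted model.
#'
#' @inheritParams counterfactual_feedback
#' @param climates scenarios to evaluate.
#' @return data.frame: `climate`, `swap_set`, `pred_disturbed_sum`,
#'   `pred_undisturbed_sum`, `percent_effect`, `ci_lo`, `ci_hi`.
#' @export
decompose_feedback <- function(model, experiment,
                               climates = experiment$design$climates,
                               window_yr = 50, n_boot = 500) {
  rows <- list()
  for (cl in climates) {
    for (ss in names(BL_SWAP_SETS)) {
      fb <- counterfactual_feedback(model, experiment, ss, cl, window_yr,
                                    n_boot)
      rows[[length(rows) + 1]] <- data.frame(
        climate = cl, swap_set = ss,
        pred_disturbed_sum = fb$pred_disturbed_sum,
        pred_undisturbed_sum = fb$pred_undisturbed_sum,
        percent_effect = fb$percent_effect,
        ci_lo = fb$ci[1], ci_hi = fb$ci[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PCA of indicator trajectories
#'
#' Standardises the eight indicator columns (zero mean, unit variance;
#' constant columns are dropped with a warning) and performs a principal
#' component analysis of the correlation matrix, returning explained
#' variance fractions, loadings and per-row scores. Typically applied to
#' per-(arm, timestep) indicator means to visualise how disturbed and
#' undisturbed trajectories diverge in indicator space.
#'
#' @param indicator_means data.frame containing the eight indicator
#'   columns; other columns (e.g. `arm`, `year`) are carried through to
#'   the scores.
#' @return object of class `bl_pca`: list with `explained` (fractions,
#'   non-increasing), `loadings`, `scores` (data.frame), `dropped`.
#' @export
pca_trajectories <- function(indicator_means) {
  cols <- intersect(BL_INDICATORS, names(indicator_means))
  if (nrow(indicator_means) < 3) stop("need at least 3 rows")
  x <- as.matrix(indicator_means[, cols])
  sds <- apply(x, 2, stats::sd)
  dropped <- cols[sds == 0]
  if (length(dropped)) {
    warning("dropping constant columns: ", paste(dropped, collapse = ", "))
  }
  keep <- cols[sds > 0]
  p <- stats::prcomp(x[, keep], center = TRUE, scale. = TRUE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  meta <- indicator_means[, setdiff(names(indicator_means), cols), drop = FALSE]
  structure(list(explained = expl,
                 loadings = p$rotation,
                 scores = cbind(meta, as.data.frame(p$x)),
                 dropped = dropped),
            class = "bl_pca")
}

#' @export
print.bl_pca <- function(x, ...) {
  cat(sprintf("<bl_pca> first two axes explain %.1f %% (%s)\n",
              100 * sum(x$explained[1:min(2, length(x$explained))]),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = " + ")))
  invisible(x)
}

#' Ground-truth benchmark of the counterfactual procedure
#'
#' Generates paired "disturbed"/"undisturbed" covariate tables from a known
#' generative response function, so the true counterfactual percent effect
#' is available in closed form, then runs the surrogate pipeline
#' (fit on disturbed rows, counterfactual prediction) and reports
#' estimation error, bias and bootstrap-CI coverage over repeated seeds.
#'
#' @param g_spec list with `fun` (function of a covariate data.frame
#'   returning the noiseless response), `shift` (named numeric: additive
#'   mean shift applied to the swapped columns to form the undisturbed
#'   table) and optionally `swap_set` (default `"all"`).
#' @param n_rows training rows per seed.
#' @param noise_sd response noise standard deviation.
#' @param seed base seed; seed `seed + i` is used for repetition i.
#' @param n_seeds number of repetitions.
#' @param ntree trees per forest (smaller than the analysis default; the
#'   benchmark fits many forests).
#' @return object of class `bl_benchmark`: list with `per_seed` (data.frame
#'   `seed`, `true_effect`, `estimated_effect`, `ci_lo`, `ci_hi`,
#'   `covered`), `bias`, `median_abs_error`, `coverage`.
#' @export
synthetic_feedback_benchmark <- function(g_spec, n_rows = 300,
                                         noise_sd = 5, seed = 1L,
                                         n_seeds = 20, ntree = 200) {
  if (!is.function(g_spec$fun)) config_error("g_spec$fun must be a function")
  if (is.null(g_spec$shift) || is.null(names(g_spec$shift))) {
    config_error("g_spec$shift must be a named numeric vector")
  }
  swap_set <- if (is.null(g_spec$swap_set)) "all" else g_spec$swap_set
  swap_cols <- BL_SWAP_SETS[[swap_set]]
  bad <- setdiff(names(g_spec$shift), swap_cols)
  if (length(bad)) config_error("shifted columns outside the swap set")

  one <- function(s) {
    set.seed(s)
    dist <- benchmark_covariates(n_rows)
    undist <- dist
    for (cl in names(g_spec$shift)) {
      undist[[cl]] <- clamp_indicator(undist[[cl]] + g_spec$shift[[cl]], cl)
    }
    mu_d <- g_spec$fun(dist)
    mu_u <- g_spec$fun(undist)
    true_eff <- 100 * (sum(mu_d) - sum(mu_u)) / sum(mu_u)
    dist$kill_m3_ha <- pmax(0, mu_d + stats::rnorm(n_rows, 0, noise_sd))
    model <- fit_surrogate(dist, ntree = ntree, seed = s)
    ya <- predict(model, dist)
    yb_tab <- dist
    yb_tab[, names(g_spec$shift)] <- undist[, names(g_spec$shift)]
    yb <- predict(model, yb_tab)
    est <- 100 * (sum(ya) - sum(yb)) / sum(yb)
    boot <- replicate(200, {
      i <- sample.int(n_rows, replace = TRUE)
      100 * (sum(ya[i]) - sum(yb[i])) / sum(yb[i])
    })
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
    data.frame(seed = s, true_effect = true_eff, estimated_effect = est,
               ci_lo = ci[1], ci_hi = ci[2],
               covered = ci[1] <= true_eff & true_eff <= ci[2])
  }
  per_seed <- do.call(rbind, lapply(seed + seq_len(n_seeds) - 1L, one))
  err <- per_seed$estimated_effect - per_seed$true_effect
  structure(list(per_seed = per_seed, bias = mean(err),
                 median_abs_error = stats::median(abs(err)),
                 coverage = mean(per_seed$covered)),
            class = "bl_benchmark")
}

#' @export
print.bl_benchmark <- function(x, ...) {
  cat(sprintf("<bl_benchmark> %d seeds: bias %.2f, median |error| %.2f pp, coverage %.2f\n",
              nrow(x$per_seed), x$bias, x$median_abs_error, x$coverage))
  invisible(x)
}

## random covariate table spanning plausible indicator ranges
benchmark_covariates <- function(n) {
  data.frame(
    climate = "BC", replicate = rep(seq_len(max(1, n %/% 10)), length.out = n),
    window = 1L,
    AlpHei = stats::runif(n, 0, 2), AlpDbh = stats::runif(n, 0, 2.2),
    CanCov = stats::runif(n, 0.2, 1), RumInd = stats::runif(n, 1, 1.3),
    BetHei = stats::runif(n, 1, 4), BetDbh = stats::runif(n, 1, 4),
    ProSpr = stats::runif(n, 0, 100), AggInd = stats::runif(n, 0, 100),
    t_mean_window_c = stats::runif(n, 4, 11),
    precip_window_mm = stats::runif(n, 50000, 90000))
}

clamp_indicator <- function(x, col) {
  lo <- c(AlpHei = 0, AlpDbh = 0, CanCov = 0, RumInd = 1, BetHei = 1,
          BetDbh = 1, ProSpr = 0, AggInd = 0)
  hi <- c(AlpHei = Inf, AlpDbh = Inf, CanCov = 1, RumInd = Inf, BetHei = Inf,
          BetDbh = Inf, ProSpr = 100, AggInd = 100)
  pmin(hi[[col]], pmax(lo[[col]], x))
}
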