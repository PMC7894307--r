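# synthetic experiment with controllable covariates for the surrogate
# pipeline: indicator snapshots at years 0/50/100 (two 50-yr windows)
make_cov_experiment <- function(n_reps = 5, climates = c("BC", "HC"),
                                seed = 1, prospr_gap = 30) {
  set.seed(seed)
  horizon <- 100L
  snap <- function(prospr, noise) {
    data.frame(year = c(0, 50, 100),
               AlpHei = runif(3, 0.5, 1.5), AlpDbh = runif(3, 0.5, 1.5),
               CanCov = runif(3, 0.5, 1), RumInd = runif(3, 1, 1.2),
               BetHei = runif(3, 1.5, 3), BetDbh = runif(3, 2, 5),
               ProSpr = prospr, AggInd = pmin(100, pmax(0, prospr + noise)))
  }
  runs <- list()
  for (cl in climates) {
    for (r in seq_len(n_reps)) {
      pro_u <- runif(3, 40, 90)
      pro_d <- pmax(0, pro_u - prospr_gap * c(0, 1, 1))
      clim <- data.frame(year = 1:horizon,
                         t_mean_c = rnorm(horizon, if (cl == "BC") 6 else 10, 0.5),
                         precip_mm = rnorm(horizon, 1400, 100))
      for (d in c(TRUE, FALSE)) {
        pro <- if (d) pro_d else pro_u
        ind <- snap(pro, rnorm(3, 0, 2))
        kill <- if (d) rep(pro[1:2] * 0.02, each = 50) else rep(0, horizon)
        runs[[beetlescape:::run_key(cl, d, r)]] <- list(
          climate_name = cl, disturbed = d, replicate = r,
          annual_kill = kill, annual_wind = rep(0, horizon),
          indicators = ind, events = NULL, climate = clim)
      }
    }
  }
  structure(list(runs = runs,
                 design = list(climates = climates, horizon_yr = horizon,
                               indicator_step_yr = 50L, replicates = n_reps,
                               base_seed = 1L)),
            class = "bl_experiment")
}

test_that("training table has one aligned row per climate/replicate/window", {
  exp <- make_cov_experiment(n_reps = 3)
  tab <- build_training_table(exp, 50)
  expect_equal(nrow(tab), 2 * 3 * 2)      # climates x replicates x windows
  expect_false(anyNA(tab))
  # hand oracle for one row: window 2 of HC replicate 2
  run <- beetlescape:::get_run(exp, "HC", TRUE, 2)
  row <- tab[tab$climate == "HC" & tab$replicate == 2 & tab$window == 2, ]
  expect_equal(row$kill_m3_ha, sum(run$annual_kill[51:100]), tolerance = 1e-12)
  expect_equal(row$ProSpr, run$indicators$ProSpr[run$indicators$year == 50],
               tolerance = 1e-12)
  expect_equal(row$t_mean_window_c, mean(run$climate$t_mean_c[51:100]),
               tolerance = 1e-12)
  expect_equal(row$precip_window_mm, sum(run$climate$precip_mm[51:100]),
               tolerance = 1e-12)
  # undisturbed runs never enter the training table
  expect_true(all(tab$kill_m3_ha > 0))
  expect_error(build_training_table(exp, 25), "indicator_step")
})

test_that("surrogate learns signal, rejects noise, and is reproducible", {
  set.seed(2)
  covs <- beetlescape:::benchmark_covariates(500)
  covs$kill_m3_ha <- 3 * covs$ProSpr + 10
  m <- fit_surrogate(covs, ntree = 300, seed = 5)
  expect_gt(m$oob_r2, 0.9)

  covs$kill_m3_ha <- rnorm(500)
  m0 <- fit_surrogate(covs, ntree = 300, seed = 5)
  expect_lt(abs(m0$oob_r2), 0.1)

  m1 <- fit_surrogate(covs, ntree = 100, seed = 9)
  m2 <- fit_surrogate(covs, ntree = 100, seed = 9)
  expect_identical(predict(m1, covs[1:20, ]), predict(m2, covs[1:20, ]))

  covs$kill_m3_ha <- 7
  expect_warning(mc <- fit_surrogate(covs, ntree = 50, seed = 1), "constant")
  expect_equal(predict(mc, covs[1:3, ]), rep(7, 3))
})

test_that("identical disturbed/undisturbed covariates give zero feedback", {
  exp <- make_cov_experiment(n_reps = 15, prospr_gap = 0)
  # force undisturbed indicators identical to disturbed
  for (key in names(exp$runs)) {
    if (!exp$runs[[key]]$disturbed) {
      dk <- sub("undisturbed", "disturbed", key)
      exp$runs[[key]]$indicators <- exp$runs[[dk]]$indicators
    }
  }
  tab <- build_training_table(exp, 50)
  tab$kill_m3_ha <- tab$kill_m3_ha + runif(nrow(tab))  # avoid degenerate fit
  m <- fit_surrogate(tab, ntree = 100, seed = 3)
  fb <- counterfactual_feedback(m, exp, "all", "HC", 50, n_boot = 50)
  expect_equal(fb$percent_effect, 0, tolerance = 1e-9)
})

test_that("covariates the response ignores produce (near) zero feedback", {
  set.seed(4)
  exp <- make_cov_experiment(n_reps = 15, prospr_gap = 40)
  tab <- build_training_table(exp, 50)
  # response depends only on climate, not on any indicator
  tab$kill_m3_ha <- 5 * tab$t_mean_window_c + rnorm(nrow(tab), 0, 0.5)
  for (key in names(exp$runs)) {
    run <- exp$runs[[key]]
    if (run$disturbed) {
      exp$runs[[key]]$annual_kill <- rep(
        5 * mean(run$climate$t_mean_c) / 50, 100)
    }
  }
  m <- fit_surrogate(tab, ntree = 300, seed = 6)
  fb <- counterfactual_feedback(m, exp, "all", "HC", 50, n_boot = 50)
  expect_lt(abs(fb$percent_effect), 5)
})

test_that("feedback decomposition attributes a ProSpr-driven response to composition", {
  set.seed(8)
  exp <- make_cov_experiment(n_reps = 15, prospr_gap = 35)
  tab <- build_training_table(exp, 50)
  tab$kill_m3_ha <- 2 * tab$ProSpr + rnorm(nrow(tab), 0, 2)
  m <- fit_surrogate(tab, ntree = 300, seed = 7)
  fb <- decompose_feedback(m, exp, climates = "HC", window_yr = 50,
                           n_boot = 50)
  eff <- setNames(fb$percent_effect, fb$swap_set)
  expect_lt(eff[["all"]], 0)              # disturbed has less spruce -> less kill
  expect_lt(eff[["composition_only"]], 0)
  expect_lt(abs(eff[["structure_only"]]), 5)
  expect_lt(abs(eff[["composition_only"]] - eff[["all"]]), 6)
})

test_that("feedback estimate is invariant to replicate relabeling", {
  set.seed(10)
  exp <- make_cov_experiment(n_reps = 15, prospr_gap = 30)
  tab <- build_training_table(exp, 50)
  m <- fit_surrogate(tab, ntree = 100, seed = 2)
  fb1 <- counterfactual_feedback(m, exp, "all", "HC", 50, n_boot = 10)
  # swap replicates 1 and 2 (both arms, keeping pairs intact)
  perm <- exp
  for (cl in c("BC", "HC")) for (d in c(TRUE, FALSE)) {
    k1 <- beetlescape:::run_key(cl, d, 1); k2 <- beetlescape:::run_key(cl, d, 2)
    tmp <- perm$runs[[k1]]; perm$runs[[k1]] <- perm$runs[[k2]]
    perm$runs[[k2]] <- tmp
    perm$runs[[k1]]$replicate <- 1L; perm$runs[[k2]]$replicate <- 2L
  }
  fb2 <- counterfactual_feedback(m, perm, "all", "HC", 50, n_boot = 10)
  expect_equal(fb1$percent_effect, fb2$percent_effect, tolerance = 1e-9)
})

test_that("PCA of indicator trajectories matches an eigendecomposition oracle", {
  set.seed(12)
  x <- as.data.frame(matrix(rnorm(13 * 8), 13, 8))
  names(x) <- BL_INDICATORS
  p <- pca_trajectories(x)
  ev <- eigen(cor(as.matrix(x)))$values
  expect_equal(p$explained, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-9)

  # perfectly collinear data: one axis carries everything
  t <- seq_len(10)
  lin <- data.frame(AlpHei = t, AlpDbh = 2 * t, CanCov = -t, RumInd = t,
                    BetHei = 3 * t, BetDbh = t, ProSpr = -2 * t, AggInd = t)
  p1 <- pca_trajectories(lin)
  expect_equal(p1$explained[1], 1, tolerance = 1e-10)

  cst <- x; cst$RumInd <- 1
  expect_warning(p2 <- pca_trajectories(cst), "constant")
  expect_false("RumInd" %in% rownames(p2$loadings))

  # scores are an isometry of the standardised data
  d_scores <- dist(p$scores[, paste0("PC", 1:8)])
  d_std <- dist(scale(as.matrix(x)))
  expect_equal(as.vector(d_scores), as.vector(d_std), tolerance = 1e-10)
})

test_that("benchmark recovers a known ProSpr-mediated effect", {
  g <- list(fun = function(d) 60 + 1.2 * d$ProSpr, shift = c(ProSpr = 30),
            swap_set = "all")
  bm <- synthetic_feedback_benchmark(g, n_rows = 300, noise_sd = 5, seed = 3,
                                     n_seeds = 5, ntree = 150)
  expect_lt(bm$median_abs_error, 10)
  expect_true(all(bm$per_seed$true_effect < 0))

  g0 <- list(fun = function(d) 60 + 1.2 * d$ProSpr, shift = c(ProSpr = 0))
  bm0 <- synthetic_feedback_benchmark(g0, n_rows = 200, noise_sd = 2, seed = 4,
                                      n_seeds = 3, ntree = 100)
  expect_equal(bm0$per_seed$true_effect, rep(0, 3))
  expect_lt(max(abs(bm0$per_seed$estimated_effect)), 3)

  gc <- list(fun = function(d) 20 + 5 * d$t_mean_window_c,
             shift = c(ProSpr = 30))
  bmc <- synthetic_feedback_benchmark(gc, n_rows = 200, noise_sd = 2, seed = 5,
                                      n_seeds = 3, ntree = 100)
  expect_lt(max(abs(bmc$per_seed$estimated_effect)), 5)
})
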