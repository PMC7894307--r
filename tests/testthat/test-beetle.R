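params <- default_config()$beetle

test_that("voltinism is a floor function of degree days with a cap", {
  g <- params$dd_per_generation
  expect_equal(thermal_generations(0, params), 0)
  expect_equal(thermal_generations(g, params), 1)
  expect_equal(thermal_generations(2 * g - 1, params), 1)
  # exhaustive sweep: non-decreasing step function with steps at multiples of g
  dd <- seq(0, 4 * g, by = 7)
  gen <- thermal_generations(dd, params)
  expect_true(all(diff(gen) >= 0))
  expect_equal(gen, pmin(params$max_generations, dd %/% g))
  expect_error(thermal_generations(-1, params), ">= 0")
})

test_that("winter survival is a logistic curve in the winter minimum", {
  expect_equal(winter_survival(params$winter_t50, params), 0.5)
  expect_lt(winter_survival(params$winter_t50 - 20 / params$winter_slope,
                            params), 0.01)
  ts <- seq(-40, 10, by = 0.25)
  s <- winter_survival(ts, params)
  expect_true(all(s > 0 & s < 1))
  expect_true(all(diff(s) > 0))          # numeric derivative everywhere > 0
  expect_error(winter_survival(NA_real_, params), "non-finite")
})

test_that("dispersal preserves a uniform field away from the edge", {
  p <- matrix(5, 11, 11)
  out <- disperse_pressure(p, params)
  r <- params$kernel_radius_cells
  interior <- out[(r + 1):(11 - r), (r + 1):(11 - r)]
  expect_equal(as.vector(interior), rep(5, length(interior)), tolerance = 1e-12)
})

test_that("dispersal conserves mass and ranks rings correctly", {
  p <- matrix(0, 11, 11); p[6, 6] <- 100
  out <- disperse_pressure(p, params)
  expect_equal(sum(out), 100, tolerance = 1)     # within 1 %
  natal <- out[6, 6]
  ring1 <- c(out[5, 5:7], out[7, 5:7], out[6, 5], out[6, 7])
  ring2 <- c(out[4, 4:8], out[8, 4:8], out[5:7, 4], out[5:7, 8])
  expect_true(all(natal >= ring1))
  expect_true(all(min(ring1) >= max(ring2)))
})

test_that("dispersal matches a direct convolution oracle on a 9x9 grid", {
  set.seed(13)
  p <- matrix(runif(81, 0, 10), 9, 9)
  k <- beetlescape:::dispersal_kernel(params, 100)
  expect_equal(disperse_pressure(p, params), oracle_conv(p, k),
               tolerance = 1e-10)
  bad <- params; bad$kernel_length_m <- -5
  expect_error(disperse_pressure(p, bad), "kernel")
})

test_that("cells without host are never killed", {
  cfg <- default_config()
  L <- make_uniform_landscape(4, 4, species = 2L)   # pure beech
  P <- matrix(1000, 4, 4)
  set.seed(3)
  res <- colonize_and_kill(L, P, climate_row(), cfg)
  expect_equal(nrow(res$records), 0)
  expect_true(all(res$kill_grid == 0))
})

test_that("drought weakens defence: drier cells lose at least as much", {
  cfg <- default_config()
  L <- make_uniform_landscape(4, 4, dbh = 30, stems = 400)
  P <- matrix(25, 4, 4)
  set.seed(4)
  wet <- colonize_and_kill(L, P, climate_row(drought = 1), cfg)
  set.seed(4)
  dry <- colonize_and_kill(L, P, climate_row(drought = 0.6), cfg)
  expect_true(all(dry$kill_grid >= wet$kill_grid - 1e-9))
})

test_that("kill follows the closed-form surplus rule and is capped by host volume", {
  cfg <- default_config()
  cfg$beetle$attack_margin <- 0            # deterministic attack
  L <- make_uniform_landscape(3, 3, dbh = 30, stems = 400)
  hostba <- as.vector(host_layers(L)$basal_area)[1]
  D <- cfg$beetle$defence_d0 * hostba * 1
  P <- matrix(D + 2 / cfg$beetle$c_kill, 3, 3)
  res <- colonize_and_kill(L, P, climate_row(drought = 1), cfg)
  expect_equal(as.vector(res$kill_grid), rep(2, 9), tolerance = 1e-9)

  # a huge surplus is capped at the standing host volume
  P2 <- matrix(1e6, 3, 3)
  res2 <- colonize_and_kill(L, P2, climate_row(drought = 1), cfg)
  hv <- as.vector(host_layers(L)$volume)
  expect_equal(as.vector(res2$kill_grid), hv, tolerance = 1e-9)
})

test_that("a hostless landscape is absorbing for outbreaks", {
  cfg <- default_config()
  L <- make_uniform_landscape(5, 5, species = 2L)
  beetles <- new_beetle_state(5, 5, cfg$beetle$background)
  beetles$pressure[3, 3] <- 500
  set.seed(6)
  for (y in 1:5) {
    res <- annual_beetle_step(L, climate_row(), NULL, beetles, cfg)
    L <- res$state; beetles <- res$beetles
    expect_equal(nrow(res$records), 0)
  }
  expect_true(all(beetles$pressure == 0))  # only background re-enters yearly
})

test_that("beetle step is deterministic given identical inputs and seed", {
  cfg <- default_config()
  L <- generate_initial_landscape(tiny_config(8, 8), 5)
  beetles <- new_beetle_state(8, 8, cfg$beetle$background)
  beetles$pressure[4, 4] <- 80
  set.seed(11)
  a <- annual_beetle_step(L, climate_row(dd = 1300), NULL, beetles, cfg)
  set.seed(11)
  b <- annual_beetle_step(L, climate_row(dd = 1300), NULL, beetles, cfg)
  expect_identical(a, b)
})

test_that("warmer climate yields more beetle kill (replicated sign test)", {
  cfg <- tiny_config(12, 12, horizon = 60, reps = 1)
  kill_bc <- kill_hc <- numeric(10)
  for (r in 1:10) {
    rb <- beetlescape:::simulate_run(
      scenario_spec("BC", TRUE, 60, 30, 1, 100 + r), cfg, 1)
    rh <- beetlescape:::simulate_run(
      scenario_spec("HC", TRUE, 60, 30, 1, 100 + r), cfg, 1)
    kill_bc[r] <- sum(rb$annual_kill)
    kill_hc[r] <- sum(rh$annual_kill)
  }
  tt <- t.test(kill_hc, kill_bc, paired = TRUE, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})

test_that("severe outbreak years deplete hosts and damp subsequent kill", {
  cfg <- tiny_config(12, 12)
  r <- beetlescape:::simulate_run(scenario_spec("HC", TRUE, 150, 50, 1, 7),
                                  cfg, 1)
  k <- r$annual_kill
  peak <- which.max(k[20:130]) + 19
  after <- mean(k[(peak + 5):(peak + 10)])
  expect_lt(after, k[peak])
})
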