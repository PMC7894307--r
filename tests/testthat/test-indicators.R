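test_that("shannon entropy matches the direct-summation oracle", {
  expect_equal(shannon_index(c(5)), 0)
  expect_equal(shannon_index(c(2, 2)), log(2), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 2, 3, 4)), oracle_shannon(c(1, 2, 3, 4)),
               tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), "all weights zero")
  expect_error(shannon_index(c(-1, 2)), "non-negative")
})

test_that("class binning is half-open with 4-unit classes", {
  co <- data.frame(cell = 1L, species = 1L, stems = c(100, 200),
                   dbh = c(10, 10), height = c(3, 5), age = 1)
  w <- class_distribution(co, "height", 4)
  expect_named(w, c("0", "4"))
  ba <- 100 * pi * (10 / 200)^2
  expect_equal(unname(w), c(ba, 2 * ba), tolerance = 1e-12)

  # value exactly on a boundary belongs to the upper class
  co2 <- data.frame(cell = 1L, species = 1L, stems = 100, dbh = 10,
                    height = 4, age = 1)
  expect_named(class_distribution(co2, "height", 4), "4")
  expect_length(class_distribution(co[0, ], "height", 4), 0)
})

test_that("alpha diversity equals the cell-loop oracle", {
  expect_equal(alpha_diversity(make_uniform_landscape(), "height"), 0)
  for (seed in 1:5) {
    L <- make_toy_landscape(5, 5, seed = seed)
    expect_equal(alpha_diversity(L, "height"), oracle_alpha(L, "height", 4),
                 tolerance = 1e-12)
    expect_equal(alpha_diversity(L, "dbh"), oracle_alpha(L, "dbh", 4),
                 tolerance = 1e-12)
  }
  empty <- new_landscape(3, 3, make_toy_landscape(2, 2)$cohorts[0, ], rep(1, 9))
  expect_error(alpha_diversity(empty, "height"), "undefined landscape")
})

test_that("beta diversity: no turnover gives 1, complete turnover counts cells", {
  expect_equal(beta_diversity(make_uniform_landscape(), "height"), 1,
               tolerance = 1e-12)
  # two cells with disjoint single classes: gamma = 2, alpha-bar = 1
  co <- data.frame(cell = c(1L, 2L), species = 1L, stems = 100,
                   dbh = c(10, 10), height = c(2, 30), age = 1)
  L <- new_landscape(2, 2, co, rep(1, 4))
  expect_equal(beta_diversity(L, "height"), 2, tolerance = 1e-12)
})

test_that("beta diversity matches the pooled-distribution oracle and is >= 1", {
  for (seed in 1:8) {
    L <- make_toy_landscape(6, 6, seed = 20 + seed)
    for (att in c("height", "dbh")) {
      expect_equal(beta_diversity(L, att), oracle_beta(L, att, 4),
                   tolerance = 1e-10)
      expect_gte(beta_diversity(L, att), 1 - 1e-12)
    }
  }
})

test_that("canopy cover follows the saturating closed form", {
  k <- 0.07
  empty <- new_landscape(3, 3, make_toy_landscape(2, 2)$cohorts[0, ], rep(1, 9))
  expect_equal(canopy_cover(empty, k), 0)
  # BA chosen so that cover is exactly one half
  ba_half <- log(2) / k
  dbh <- 30
  stems <- ba_half / (pi * (dbh / 200)^2)
  L <- make_uniform_landscape(3, 3, stems = stems, dbh = dbh)
  expect_equal(canopy_cover(L, k), 0.5, tolerance = 1e-10)
  # monotone saturation toward 1
  L2 <- make_uniform_landscape(3, 3, stems = 10 * stems, dbh = dbh)
  expect_gt(canopy_cover(L2, k), canopy_cover(L, k))
  expect_lt(canopy_cover(L2, k), 1)
})

test_that("rumple index matches the hand-triangulation oracle", {
  flat <- make_height_landscape(matrix(25, 3, 3))
  expect_equal(rumple_index(flat), 1, tolerance = 1e-12)

  h <- matrix(c(0, 0, 0, 40), 2, 2)
  expect_equal(rumple_index(make_height_landscape(h)), oracle_rumple(h),
               tolerance = 1e-10)
  for (seed in 1:5) {
    set.seed(seed)
    hm <- matrix(runif(20, 0, 45), 4, 5)
    L <- make_height_landscape(hm)
    expect_equal(rumple_index(L), oracle_rumple(hm), tolerance = 1e-10)
    expect_gte(rumple_index(L), 1)
  }
  narrow <- make_height_landscape(matrix(10, 2, 5))
  narrow$nrow <- 1L   # degenerate 1 x N strip
  expect_error(rumple_index(narrow), "2 x 2")
})

test_that("spruce proportion and aggregation index handle the pure cases", {
  pure <- make_uniform_landscape(3, 3, species = 1L)
  none <- make_uniform_landscape(3, 3, species = 2L)
  expect_equal(spruce_proportion(pure), 100)
  expect_equal(spruce_proportion(none), 0)
  expect_equal(aggregation_index(pure), 100)
  expect_equal(aggregation_index(none), 0)
})

test_that("aggregation index counts 8-connected clusters of size >= 2", {
  mk <- function(cells) {
    co <- data.frame(cell = cells, species = 1L, stems = 300, dbh = 30,
                     height = 25, age = 60)
    new_landscape(3, 3, co, rep(1, 9))
  }
  # corners (1,1) and (3,3): diagonally non-adjacent singletons
  expect_equal(aggregation_index(mk(c(1L, 9L))), 0)
  # (1,1) and (2,2) touch diagonally: 2 of 9 cells
  expect_equal(aggregation_index(mk(c(1L, 5L))), 100 * 2 / 9, tolerance = 1e-12)
  # min_cluster = 1 counts singletons too
  expect_equal(aggregation_index(mk(c(1L, 9L)), min_cluster = 1),
               100 * 2 / 9, tolerance = 1e-12)
})

test_that("aggregation index agrees with a BFS flood-fill oracle", {
  for (seed in 1:10) {
    set.seed(40 + seed)
    nr <- sample(3:7, 1); nc <- sample(3:7, 1)
    host <- matrix(runif(nr * nc) < 0.4, nr, nc)
    cells <- which(host)
    L <- if (length(cells)) {
      new_landscape(nr, nc, data.frame(cell = cells, species = 1L,
                                       stems = 300, dbh = 30, height = 25,
                                       age = 60), rep(1, nr * nc))
    } else {
      new_landscape(nr, nc, make_toy_landscape(2, 2)$cohorts[0, ],
                    rep(1, nr * nc))
    }
    expect_equal(aggregation_index(L), oracle_aggind(host), tolerance = 1e-12)
  }
})

test_that("indicator vector composes the individual indicators consistently", {
  cfg <- default_config()
  L <- make_toy_landscape(5, 5, seed = 77)
  iv <- indicator_vector(L, cfg)
  expect_equal(iv$AlpHei, alpha_diversity(L, "height"), tolerance = 1e-12)
  expect_equal(iv$BetDbh, beta_diversity(L, "dbh"), tolerance = 1e-12)
  expect_equal(iv$CanCov, canopy_cover(L, cfg$indicators$k_cov),
               tolerance = 1e-12)
  expect_equal(iv$RumInd, rumple_index(L), tolerance = 1e-12)
  expect_equal(iv$ProSpr, spruce_proportion(L), tolerance = 1e-12)
  expect_equal(iv$AggInd, aggregation_index(L), tolerance = 1e-12)

  # uniform pure-spruce landscape forces all degenerate values
  U <- make_uniform_landscape(4, 4, species = 1L, dbh = 30, height = 25)
  ivu <- indicator_vector(U, cfg)
  expect_equal(unname(unlist(ivu[BL_INDICATORS])),
               c(0, 0, canopy_cover(U, cfg$indicators$k_cov), 1, 1, 1, 100, 100),
               tolerance = 1e-10)

  empty <- new_landscape(3, 3, make_toy_landscape(2, 2)$cohorts[0, ], rep(1, 9))
  expect_error(indicator_vector(empty, cfg))
})

test_that("indicators are invariant under grid rotation and reflection", {
  cfg <- default_config()
  L <- make_toy_landscape(5, 5, seed = 99)
  rot <- function(state) {
    nr <- state$nrow; nc <- state$ncol
    co <- state$cohorts
    r <- ((co$cell - 1L) %% nr) + 1L
    c <- ((co$cell - 1L) %/% nr) + 1L
    # 90-degree rotation: (r, c) -> (c, nr + 1 - r) on an nc x nr grid
    co$cell <- (nr + 1L - r - 1L) * nc + c
    new_landscape(nc, nr, co, rep(1, nr * nc))
  }
  refl <- function(state) {
    nr <- state$nrow; nc <- state$ncol
    co <- state$cohorts
    r <- ((co$cell - 1L) %% nr) + 1L
    c <- ((co$cell - 1L) %/% nr) + 1L
    co$cell <- (c - 1L) * nr + (nr + 1L - r)
    new_landscape(nr, nc, co, rep(1, nr * nc))
  }
  for (L2 in list(rot(L), refl(L))) {
    a <- unlist(indicator_vector(L, cfg)[BL_INDICATORS])
    b <- unlist(indicator_vector(L2, cfg)[BL_INDICATORS])
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("removing all spruce zeroes the compositional indicators", {
  cfg <- default_config()
  L <- make_toy_landscape(5, 5, seed = 55, p_spruce = 0.6)
  L2 <- L
  L2$cohorts <- L2$cohorts[L2$cohorts$species != 1L, ]
  expect_equal(spruce_proportion(L2), 0)
  expect_equal(aggregation_index(L2), 0)
  expect_lte(canopy_cover(L2), canopy_cover(L))
})
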