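# Independent brute-force oracles used to verify the indicator and
# dispersal implementations, plus small toy-landscape builders. The
# oracles deliberately use naive loops and direct formulas, sharing no
# code with the package implementation.

# direct-summation Shannon entropy
oracle_shannon <- function(w) {
  p <- w / sum(w)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

# brute-force per-cell basal-area binning (half-open classes [k*w,(k+1)*w))
oracle_bins <- function(cohorts, attribute, width) {
  out <- list()
  for (i in seq_len(nrow(cohorts))) {
    x <- cohorts[[attribute]][i]
    k <- as.character(floor(x / width))
    ba <- cohorts$stems[i] * pi * (cohorts$dbh[i] / 200)^2
    out[[k]] <- (if (is.null(out[[k]])) 0 else out[[k]]) + ba
  }
  unlist(out)
}

# cell-loop alpha diversity
oracle_alpha <- function(state, attribute, width) {
  hs <- c()
  for (cell in sort(unique(state$cohorts$cell))) {
    sub <- state$cohorts[state$cohorts$cell == cell, ]
    hs <- c(hs, oracle_shannon(oracle_bins(sub, attribute, width)))
  }
  mean(hs)
}

# pooled-distribution beta diversity on the effective-number scale
oracle_beta <- function(state, attribute, width) {
  cells <- sort(unique(state$cohorts$cell))
  pooled <- list()
  hs <- c()
  for (cell in cells) {
    sub <- state$cohorts[state$cohorts$cell == cell, ]
    w <- oracle_bins(sub, attribute, width)
    hs <- c(hs, oracle_shannon(w))
    p <- w / sum(w)
    for (k in names(p)) {
      pooled[[k]] <- (if (is.null(pooled[[k]])) 0 else pooled[[k]]) +
        p[[k]] / length(cells)
    }
  }
  exp(oracle_shannon(unlist(pooled))) / exp(mean(hs))
}

# hand triangulation of the canopy surface: explicit 3-D points, generic
# cross-product triangle areas; both diagonal splits averaged
oracle_rumple <- function(heights, cell_size = 100) {
  nr <- nrow(heights); nc <- ncol(heights)
  corner <- matrix(0, nr + 1, nc + 1)
  for (i in 0:(nr)) {
    for (j in 0:(nc)) {
      vals <- c()
      for (di in 0:1) for (dj in 0:1) {
        ci <- i + di; cj <- j + dj
        if (ci >= 1 && ci <= nr && cj >= 1 && cj <= nc) {
          vals <- c(vals, heights[ci, cj])
        }
      }
      corner[i + 1, j + 1] <- mean(vals)
    }
  }
  tri <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    0.5 * sqrt(sum(cr^2))
  }
  s <- cell_size
  area <- 0
  for (i in 1:nr) {
    for (j in 1:nc) {
      p_tl <- c((i - 1) * s, (j - 1) * s, corner[i, j])
      p_tr <- c((i - 1) * s, j * s, corner[i, j + 1])
      p_bl <- c(i * s, (j - 1) * s, corner[i + 1, j])
      p_br <- c(i * s, j * s, corner[i + 1, j + 1])
      split1 <- tri(p_tl, p_tr, p_bl) + tri(p_tr, p_br, p_bl)
      split2 <- tri(p_tl, p_tr, p_br) + tri(p_tl, p_br, p_bl)
      area <- area + (split1 + split2) / 2
    }
  }
  area / (nr * nc * s^2)
}

# BFS flood fill for 8-connected host clusters
oracle_aggind <- function(host, min_cluster = 2) {
  nr <- nrow(host); nc <- ncol(host)
  lab <- matrix(0L, nr, nc)
  next_lab <- 0L
  sizes <- integer()
  for (i in 1:nr) for (j in 1:nc) {
    if (host[i, j] && lab[i, j] == 0L) {
      next_lab <- next_lab + 1L
      queue <- list(c(i, j)); lab[i, j] <- next_lab; size <- 0L
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
        for (di in -1:1) for (dj in -1:1) {
          ni <- cur[1] + di; nj <- cur[2] + dj
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              host[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- next_lab
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
      sizes[next_lab] <- size
    }
  }
  if (next_lab == 0L) return(0)
  count <- 0L
  for (k in seq_len(next_lab)) if (sizes[k] >= min_cluster) count <- count + sizes[k]
  100 * count / (nr * nc)
}

# direct O(n^2 k^2) convolution with zero padding
oracle_conv <- function(mat, kernel) {
  nr <- nrow(mat); nc <- ncol(mat)
  kr <- (nrow(kernel) - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    acc <- 0
    for (di in -kr:kr) for (dj in -kr:kr) {
      si <- i - di; sj <- j - dj
      if (si >= 1 && si <= nr && sj >= 1 && sj <= nc) {
        acc <- acc + kernel[kr + 1 + di, kr + 1 + dj] * mat[si, sj]
      }
    }
    out[i, j] <- acc
  }
  out
}

# random toy landscape: nrow x ncol, 0..4 cohorts per cell
make_toy_landscape <- function(nrow = 5, ncol = 5, seed = 1,
                               p_empty = 0.1, p_spruce = 0.5) {
  set.seed(seed)
  rows <- list()
  for (cell in seq_len(nrow * ncol)) {
    if (runif(1) < p_empty) next
    n <- sample(1:4, 1)
    for (k in seq_len(n)) {
      dbh <- runif(1, 2, 60)
      rows[[length(rows) + 1]] <- data.frame(
        cell = cell,
        species = if (runif(1) < p_spruce) 1L else sample(2:4, 1),
        stems = runif(1, 20, 600), dbh = dbh,
        height = runif(1, 2, 45), age = round(dbh * 2))
    }
  }
  cohorts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(), species = integer(), stems = numeric(),
               dbh = numeric(), height = numeric(), age = numeric())
  new_landscape(nrow, ncol, cohorts, rep(1, nrow * ncol))
}

# uniform single-cohort landscape (every cell identical)
make_uniform_landscape <- function(nrow = 4, ncol = 4, species = 1L,
                                   stems = 300, dbh = 30, height = 25) {
  ncell <- nrow * ncol
  cohorts <- data.frame(cell = seq_len(ncell), species = species,
                        stems = stems, dbh = dbh, height = height,
                        age = 60)
  new_landscape(nrow, ncol, cohorts, rep(1, ncell))
}

# landscape with prescribed per-cell top heights (one cohort per cell,
# absent where height is 0)
make_height_landscape <- function(heights) {
  nr <- nrow(heights); nc <- ncol(heights)
  idx <- which(heights > 0)
  cohorts <- data.frame(cell = idx, species = 1L, stems = 300,
                        dbh = 30, height = heights[idx], age = 60)
  new_landscape(nr, nc, cohorts, rep(1, nr * nc))
}

# tiny fast config for simulation tests
tiny_config <- function(nrow = 12, ncol = 12, horizon = 60, reps = 2,
                        climates = c("BC", "HC")) {
  cfg <- default_config()
  cfg$landscape$nrow <- as.integer(nrow)
  cfg$landscape$ncol <- as.integer(ncol)
  cfg$experiment$horizon_yr <- as.integer(horizon)
  cfg$experiment$indicator_step_yr <- if (horizon %% 50 == 0) 50L else
    as.integer(horizon %/% 2)
  cfg$experiment$replicates <- as.integer(reps)
  cfg$experiment$climates <- climates
  cfg
}

# one-year climate row for direct calls
climate_row <- function(t_mean = 6, t_min = -8, precip = 1400,
                        dd = 700, drought = 1) {
  list(t_mean_c = t_mean, t_min_winter_c = t_min, precip_mm = precip,
       dd_sum = dd, drought_index = drought)
}
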