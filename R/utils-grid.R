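## Shared raster helpers used by the landscape generator, the dispersal
## kernel and the regeneration neighbourhood sums. Cells live on an
## nrow x ncol matrix at 100 m resolution; all public functions index
## cells as (row, col), 1-based.

#' 2-D convolution with zero padding
#'
#' Convolves a matrix with a (2R+1) x (2R+1) kernel, treating everything
#' outside the grid as zero. Mass falling outside the grid is lost, which
#' is the behaviour wanted for beetle dispersal at the landscape edge.
#'
#' @param mat numeric matrix.
#' @param kernel odd-sized square numeric matrix.
#' @return matrix of the same dimension as `mat`.
#' @keywords internal
conv2d <- function(mat, kernel) {
  kr <- (nrow(kernel) - 1L) / 2L
  kc <- (ncol(kernel) - 1L) / 2L
  nr <- nrow(mat)
  nc <- ncol(mat)
  pad <- matrix(0, nr + 2L * kr, nc + 2L * kc)
  pad[(kr + 1L):(kr + nr), (kc + 1L):(kc + nc)] <- mat
  out <- matrix(0, nr, nc)
  for (di in -kr:kr) {
    for (dj in -kc:kc) {
      w <- kernel[kr + 1L + di, kc + 1L + dj]
      if (w == 0) next
      out <- out + w * pad[(kr + 1L + di):(kr + nr + di),
                           (kc + 1L + dj):(kc + nc + dj)]
    }
  }
  out
}

#' Sum over the 8-cell (queen) neighbourhood
#' @param mat numeric matrix.
#' @param include_self add the focal cell's own value.
#' @keywords internal
neighbour_sum <- function(mat, include_self = FALSE) {
  k <- matrix(1, 3, 3)
  if (!include_self) k[2, 2] <- 0
  conv2d(mat, k)
}

#' Moran's I spatial autocorrelation (queen contiguity, binary weights)
#'
#' @param mat numeric matrix of a per-cell quantity.
#' @return scalar Moran's I; positive values indicate spatial clustering.
#' @export
morans_i <- function(mat) {
  z <- mat - mean(mat)
  if (all(z == 0)) return(0)
  nsum <- neighbour_sum(z)
  ones <- matrix(1, nrow(mat), ncol(mat))
  s0 <- sum(neighbour_sum(ones))          # total number of directed neighbour pairs
  n <- length(mat)
  (n / s0) * sum(z * nsum) / sum(z^2)
}

#' Smoothed Gaussian random field on a grid
#'
#' White noise convolved with a Gaussian kernel, then standardised to zero
#' mean and unit variance. Used to give the synthetic landscape spatially
#' autocorrelated species composition. Draws from the current RNG stream.
#'
#' @param nrow,ncol grid dimensions.
#' @param range_cells kernel standard deviation in cells; larger values give
#'   smoother fields.
#' @keywords internal
smooth_field <- function(nrow, ncol, range_cells = 4) {
  noise <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  r <- max(1L, ceiling(2 * range_cells))
  d <- (-r):r
  g1 <- exp(-(d^2) / (2 * range_cells^2))
  kernel <- outer(g1, g1)
  kernel <- kernel / sum(kernel)
  f <- conv2d(noise, kernel)
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

## --- RNG streams -----------------------------------------------------------
## run_scenario() keeps vegetation and disturbance randomness on separate
## streams so that a disturbed and an undisturbed replicate sharing a seed
## draw identical vegetation random numbers (common random numbers).

rng_stream <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  state <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  env <- new.env(parent = emptyenv())
  env$state <- state
  env
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
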