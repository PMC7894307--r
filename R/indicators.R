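## The eight structural and compositional diversity indicators, computed
## from a landscape snapshot:
##   AlpHei, AlpDbh — mean within-stand Shannon entropy of 4-m height /
##                    4-cm dbh classes (basal-area weighted), nats;
##   CanCov         — landscape mean canopy cover, fraction;
##   RumInd         — rumple index, canopy surface area / ground area;
##   BetHei, BetDbh — multiplicative among-stand beta diversity
##                    (gamma / alpha on the effective-number scale), >= 1;
##   ProSpr         — spruce share of total basal area, %;
##   AggInd         — share of the landscape in contiguous (8-connected,
##                    size >= 2) clusters of host cells, %.

#' Shannon entropy of a weight vector
#'
#' \eqn{H = -\sum_k p_k \ln p_k} over classes with positive weight, nats.
#'
#' @param weights non-negative weights by class.
#' @return entropy in nats, in `[0, ln(number of positive classes)]`.
#' @export
shannon_index <- function(weights) {
  if (any(weights < 0) || any(!is.finite(weights))) {
    stop("weights must be finite and non-negative")
  }
  tot <- sum(weights)
  if (tot <= 0) stop("undefined distribution: all weights zero")
  p <- weights[weights > 0] / tot
  -sum(p * log(p))
}

## class index of an attribute value: half-open bins [k*w, (k+1)*w)
class_of <- function(x, width) floor(x / width)

#' Class distribution of one cell
#'
#' Assigns each cohort's basal area to the half-open class
#' \eqn{[k w, (k+1) w)} containing its mean attribute value.
#'
#' @param cohorts cohort data.frame of one cell.
#' @param attribute `"height"` or `"dbh"`.
#' @param class_width class width (default 4 m for height, 4 cm for dbh).
#' @return named numeric vector of basal-area weights, names are the class
#'   start values; zero-length for an empty cell.
#' @export
class_distribution <- function(cohorts, attribute = c("height", "dbh"),
                               class_width = 4) {
  attribute <- match.arg(attribute)
  if (!nrow(cohorts)) return(stats::setNames(numeric(0), character(0)))
  x <- cohorts[[attribute]]
  k <- class_of(x, class_width)
  w <- rowsum(cohort_basal_area(cohorts), k)
  stats::setNames(as.numeric(w), as.numeric(rownames(w)) * class_width)
}

## per-cell entropies and normalised pooled distribution, one pass
cell_entropy_table <- function(state, attribute, class_width) {
  co <- state$cohorts
  if (!nrow(co)) stop("undefined landscape: no cohorts")
  x <- co[[attribute]]
  k <- class_of(x, class_width)
  ba <- cohort_basal_area(co)
  keep <- ba > 0
  co <- co[keep, , drop = FALSE]; k <- k[keep]; ba <- ba[keep]
  if (!length(ba)) stop("undefined landscape: no basal area")
  tot_cell <- rowsum(ba, co$cell)
  tot <- stats::setNames(as.numeric(tot_cell), rownames(tot_cell))
  p <- ba / tot[as.character(co$cell)]
  key <- paste(co$cell, k)
  pk <- rowsum(p, key)                       # per-cell class shares
  cell_of_key <- as.integer(sub(" .*", "", rownames(pk)))
  class_of_key <- as.integer(sub(".* ", "", rownames(pk)))
  h <- rowsum(-as.numeric(pk) * log(as.numeric(pk)), cell_of_key)
  ## pooled distribution with equal cell weight
  n_cells <- length(tot)
  pooled <- rowsum(as.numeric(pk) / n_cells, class_of_key)
  list(cell = as.integer(rownames(h)), H = as.numeric(h),
       pooled = stats::setNames(as.numeric(pooled), rownames(pooled)))
}

#' Mean within-stand (alpha) diversity
#'
#' Unweighted mean over non-empty cells of the per-cell Shannon entropy of
#' the binned attribute distribution.
#'
#' @param state a `bl_landscape`.
#' @param attribute `"height"` or `"dbh"`.
#' @param class_width bin width (4 m / 4 cm by default).
#' @return mean entropy, nats.
#' @export
alpha_diversity <- function(state, attribute = c("height", "dbh"),
                            class_width = 4) {
  attribute <- match.arg(attribute)
  mean(cell_entropy_table(state, attribute, class_width)$H)
}

#' Multiplicative among-stand (beta) diversity
#'
#' Computed on the effective-number scale:
#' \eqn{\gamma = e^{H(\text{pooled})}} with the pooled distribution the
#' equal-weight average of the per-cell class distributions,
#' \eqn{\bar\alpha = e^{\overline{H}_{cell}}}, and
#' \eqn{\beta = \gamma / \bar\alpha \ge 1}; \eqn{\beta = 1} when all cells
#' share the same distribution. Setting `effective_numbers = FALSE` returns
#' the raw-entropy ratio \eqn{H_\gamma / \bar H_\alpha} instead.
#'
#' @inheritParams alpha_diversity
#' @param effective_numbers logical, see above.
#' @export
beta_diversity <- function(state, attribute = c("height", "dbh"),
                           class_width = 4, effective_numbers = TRUE) {
  attribute <- match.arg(attribute)
  tab <- cell_entropy_table(state, attribute, class_width)
  h_gamma <- shannon_index(tab$pooled)
  h_alpha <- mean(tab$H)
  if (effective_numbers) exp(h_gamma) / exp(h_alpha)
  else if (h_alpha > 0) h_gamma / h_alpha else Inf
}

#' Landscape canopy cover
#'
#' Per-cell cover follows a Beer-Lambert saturation in basal area,
#' \eqn{1 - e^{-k_{cov} BA}}; the landscape value is the mean over all
#' cells (empty cells contribute 0).
#'
#' @param state a `bl_landscape`.
#' @param k_cov extinction coefficient, 1/(m2/ha).
#' @return fraction in `[0, 1]`.
#' @export
canopy_cover <- function(state, k_cov = 0.07) {
  mean(1 - exp(-k_cov * cell_basal_area(state)))
}

#' Rumple index
#'
#' Ratio of canopy surface area to ground surface area. The canopy surface
#' is a triangulated mesh over corner heights interpolated from the
#' per-cell top heights (mean of the 1, 2 or 4 adjacent cells); each cell
#' contributes two 3-D triangles. A flat canopy gives exactly 1.
#'
#' @param state a `bl_landscape`.
#' @return ratio >= 1.
#' @export
rumple_index <- function(state) {
  if (state$nrow < 2 || state$ncol < 2) {
    stop("rumple index requires a grid of at least 2 x 2 cells")
  }
  h <- top_height(state)
  rumple_from_heights(h, state$cell_size_m)
}

## surface/ground ratio of a top-height matrix (vectorised)
#' @rdname rumple_index
#' @param heights matrix of per-cell top heights, m.
#' @param cell_size_m cell edge length, m.
#' @export
rumple_from_heights <- function(heights, cell_size_m = 100) {
  nr <- nrow(heights); nc <- ncol(heights)
  corner <- corner_heights(heights)
  s <- cell_size_m
  tl <- corner[1:nr, 1:nc]; tr <- corner[1:nr, 2:(nc + 1)]
  bl <- corner[2:(nr + 1), 1:nc]; br <- corner[2:(nr + 1), 2:(nc + 1)]
  ## each cell is triangulated along both diagonals and the two surface
  ## areas averaged, so the index is exactly invariant under grid
  ## rotation and reflection; |u x v|/2 reduces to the closed forms below
  d1 <- (s / 2) * (sqrt((tr - tl)^2 + (bl - tl)^2 + s^2) +
                     sqrt((br - tr)^2 + (br - bl)^2 + s^2))
  d2 <- (s / 2) * (sqrt((tr - tl)^2 + (br - tr)^2 + s^2) +
                     sqrt((bl - tl)^2 + (br - bl)^2 + s^2))
  sum((d1 + d2) / 2) / (nr * nc * s^2)
}

## corner grid: each corner is the mean of the 1, 2 or 4 adjacent cells
corner_heights <- function(heights) {
  nr <- nrow(heights); nc <- ncol(heights)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- heights
  sub <- list(pad[1:(nr + 1), 1:(nc + 1)], pad[1:(nr + 1), 2:(nc + 2)],
              pad[2:(nr + 2), 1:(nc + 1)], pad[2:(nr + 2), 2:(nc + 2)])
  total <- count <- matrix(0, nr + 1, nc + 1)
  for (m in sub) {
    ok <- !is.na(m)
    total[ok] <- total[ok] + m[ok]
    count <- count + ok
  }
  total / count
}

#' Spruce share of total basal area
#'
#' @param state a `bl_landscape`.
#' @return percent in `[0, 100]`.
#' @export
spruce_proportion <- function(state) {
  ba <- cohort_basal_area(state$cohorts)
  tot <- sum(ba)
  if (tot <= 0) stop("undefined landscape: no basal area")
  100 * sum(ba[state$cohorts$species == 1L]) / tot
}

#' Host aggregation index
#'
#' Host cells are cells holding any spruce cohort above the host dbh
#' threshold. Clusters are 8-connected components of host cells; the index
#' is the percentage of all landscape cells belonging to components of at
#' least `min_cluster` cells (singletons are not contiguous).
#'
#' @param state a `bl_landscape`.
#' @param host_dbh_cm host threshold, cm.
#' @param min_cluster minimum component size counted, cells.
#' @return percent in `[0, 100]`.
#' @export
aggregation_index <- function(state, host_dbh_cm = 15, min_cluster = 2) {
  co <- state$cohorts
  ncell <- state$nrow * state$ncol
  host <- rep(FALSE, ncell)
  host[unique(co$cell[co$species == 1L & co$dbh > host_dbh_cm])] <- TRUE
  if (!any(host)) return(0)
  cells <- which(host)
  if (min_cluster <= 1) return(100 * length(cells) / ncell)
  nr <- state$nrow
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  ## edges to E, S, SE, SW neighbours (covers all 8-adjacencies once)
  id <- seq_along(cells)
  pos <- integer(ncell); pos[cells] <- id
  edges <- NULL
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= state$ncol
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    has <- host[nb]
    if (any(has)) edges <- rbind(edges, cbind(id[ok][has], pos[nb[has]]))
  }
  if (is.null(edges)) return(0)   # all singletons
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(cells) - igraph::vcount(g)))
  comp <- igraph::components(g)
  in_cluster <- comp$csize[comp$membership] >= min_cluster
  100 * sum(in_cluster) / ncell
}

#' All eight indicators from one snapshot
#'
#' @param state a `bl_landscape`.
#' @param config configuration list (section `indicators`).
#' @return 1-row data.frame: `year`, `AlpHei`, `AlpDbh`, `CanCov`,
#'   `RumInd`, `BetHei`, `BetDbh`, `ProSpr`, `AggInd`.
#' @export
indicator_vector <- function(state, config = default_config()) {
  ic <- config$indicators
  data.frame(
    year = state$year,
    AlpHei = alpha_diversity(state, "height", ic$height_class_m),
    AlpDbh = alpha_diversity(state, "dbh", ic$dbh_class_cm),
    CanCov = canopy_cover(state, ic$k_cov),
    RumInd = rumple_index(state),
    BetHei = beta_diversity(state, "height", ic$height_class_m,
                            ic$beta_effective_numbers),
    BetDbh = beta_diversity(state, "dbh", ic$dbh_class_cm,
                            ic$beta_effective_numbers),
    ProSpr = spruce_proportion(state),
    AggInd = aggregation_index(state, ic$host_dbh_cm, ic$aggind_min_cluster))
}
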