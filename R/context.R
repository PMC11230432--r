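# Colony-context metrics: Voronoi/Delaunay adjacency, local density,
# normalized distance from colony center (graph depth), radial height
# slope, colony-time alignment, the hexagonal-prism packing model and
# neighbourhood-averaged transient rates.

#' Voronoi-adjacency graph of one colony frame
#'
#' Nuclei are neighbours when their Voronoi cells share a ridge, i.e. when a
#' Delaunay edge connects their XY centroids. Nodes with unbounded Voronoi
#' regions (convex-hull points) are the colony boundary.
#'
#' @param x,y Centroid coordinates (um) of the non-excluded nuclei in one
#'   frame.
#' @param ids Optional node identifiers (default `seq_along(x)`).
#' @return A list of class `ng_colony_graph`: `ids`, `xy`, `edges`
#'   (two-column index matrix), `neighbors` (adjacency list),
#'   `mean_nbr_dist`, `density` (um^-2), `boundary` (logical).
#' @export
voronoi_adjacency <- function(x, y, ids = seq_along(x)) {
  n <- length(x)
  if (n < 3) stop("degenerate geometry: need at least 3 centroids")
  M <- cbind(x - mean(x), y - mean(y))
  if (abs(det(crossprod(M))) < 1e-16 * (sum(M^2) + 1)^2)
    stop("degenerate geometry: centroids are collinear")
  edges <- delaunay_edges_cpp(cbind(x, y))
  # boundary: unbounded Voronoi region = convex-hull vertex, plus nuclei
  # within half the median Delaunay edge length of the hull polygon (edge
  # nuclei perturbed slightly inwards are still colony boundary)
  hull <- grDevices::chull(x, y)
  elen <- sqrt((x[edges[, 1]] - x[edges[, 2]])^2 +
               (y[edges[, 1]] - y[edges[, 2]])^2)
  tol <- 0.5 * median(elen)
  boundary <- seq_len(n) %in% hull |
    dist_to_polygon(x, y, x[hull], y[hull]) <= tol
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    nbrs[[i]] <- c(nbrs[[i]], j)
    nbrs[[j]] <- c(nbrs[[j]], i)
  }
  nbrs <- lapply(nbrs, sort)
  mnd <- vapply(seq_len(n), function(i) {
    if (!length(nbrs[[i]])) return(NA_real_)
    mean(sqrt((x[nbrs[[i]]] - x[i])^2 + (y[nbrs[[i]]] - y[i])^2))
  }, numeric(1))
  structure(list(ids = ids, xy = cbind(x = x, y = y), edges = edges,
                 neighbors = nbrs, mean_nbr_dist = mnd,
                 density = 1 / mnd^2, boundary = boundary),
            class = "ng_colony_graph")
}

# minimum distance from each point to the boundary of the polygon with
# vertices (px, py) (in order)
dist_to_polygon <- function(x, y, px, py) {
  m <- length(px)
  best <- rep(Inf, length(x))
  for (k in seq_len(m)) {
    x1 <- px[k]; y1 <- py[k]
    x2 <- px[k %% m + 1]; y2 <- py[k %% m + 1]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx^2 + dy^2
    tt <- if (L2 == 0) rep(0, length(x))
          else pmin(pmax(((x - x1) * dx + (y - y1) * dy) / L2, 0), 1)
    d <- sqrt((x - (x1 + tt * dx))^2 + (y - (y1 + tt * dy))^2)
    best <- pmin(best, d)
  }
  best
}

#' Local density at a node
#'
#' The inverse square of the mean centroid-to-centroid distance to the
#' node's Voronoi neighbours: a per-area metric approximating local
#' density.
#'
#' @param graph An `ng_colony_graph`.
#' @param node Node index (default all nodes).
#' @return Density in um^-2 (NA for isolated nodes).
#' @export
local_density <- function(graph, node = NULL) {
  if (is.null(node)) graph$density else graph$density[node]
}

#' Approximate cell radius at a node
#'
#' Half the mean distance between the nucleus and its Voronoi neighbours'
#' centroids. Satisfies `density == 1/(2*radius)^2` exactly.
#'
#' @param graph An `ng_colony_graph`.
#' @param node Node index (default all nodes).
#' @return Radius in um (NA for isolated nodes).
#' @export
approx_cell_radius <- function(graph, node = NULL) {
  r <- graph$mean_nbr_dist / 2
  if (is.null(node)) r else r[node]
}

#' Colony depth and normalized distance from colony center
#'
#' Boundary nuclei have depth 1; interior depths grow by breadth-first
#' propagation over the adjacency (depth = 1 + graph distance to the
#' nearest boundary node). Spuriously long Delaunay edges (more than
#' `prune_factor` times the median edge length) are pruned first to
#' stabilise ragged boundaries. The normalized distance from colony center
#' is \eqn{d_N = (d_{max} - d)/(d_{max} - d_{min})}: 0 at the colony
#' center, 1 at the boundary. When every node is on the boundary
#' (`d_max == d_min`) the convention is \eqn{d_N \equiv 1}.
#'
#' @param graph An `ng_colony_graph`.
#' @param prune_factor Edge-length pruning multiplier (default 3).
#' @return List with `depth` (integer, NA if unreachable from the boundary)
#'   and `normalized_depth`.
#' @export
colony_depth <- function(graph, prune_factor = 3) {
  n <- nrow(graph$xy)
  e <- graph$edges
  len <- sqrt((graph$xy[e[, 1], 1] - graph$xy[e[, 2], 1])^2 +
              (graph$xy[e[, 1], 2] - graph$xy[e[, 2], 2])^2)
  keep <- len <= prune_factor * median(len)
  e <- e[keep, , drop = FALSE]
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  depth <- rep(NA_integer_, n)
  frontier <- which(graph$boundary)
  depth[frontier] <- 1L
  cur <- 1L
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(depth[nxt])]
    if (!length(nxt)) break
    depth[nxt] <- cur + 1L
    frontier <- nxt
    cur <- cur + 1L
  }
  dmax <- max(depth, na.rm = TRUE)
  dmin <- min(depth, na.rm = TRUE)
  dn <- if (dmax > dmin) (dmax - depth) / (dmax - dmin)
        else rep(1, n) # all-boundary colony: everything is at the edge
  dn[is.na(depth)] <- NA
  list(depth = depth, normalized_depth = as.numeric(dn))
}

#' Radial slope of colony height
#'
#' Ordinary least squares of nuclear height against the normalized distance
#' from colony center. A positive slope means nuclei are taller towards the
#' colony edge; strength is reported as the Pearson correlation.
#'
#' @param height Nuclear heights (um).
#' @param normalized_depth Normalized distances from colony center.
#' @return List with `slope` (um per unit `d_N`) and `pearson_r` (NA when a
#'   correlation is undefined).
#' @export
radial_height_slope <- function(height, normalized_depth) {
  ok <- !is.na(height) & !is.na(normalized_depth)
  if (sum(ok) < 3) stop("need at least 3 nuclei with height and depth")
  h <- height[ok]; dn <- normalized_depth[ok]
  if (sd(dn) == 0) return(list(slope = NA_real_, pearson_r = NA_real_))
  fit <- lm.fit(cbind(1, dn), h)
  r <- if (sd(h) == 0) NA_real_ else cor(dn, h)
  list(slope = unname(fit$coefficients[2]), pearson_r = r)
}

#' Align two colonies in time by their mean-height trajectories
#'
#' Finds the integer frame lag of series `b` relative to series `a`
#' minimising the mean squared difference over their overlap. A positive
#' lag means `b` is delayed: `b[i + lag]` lines up with `a[i]`.
#'
#' @param a,b Numeric per-frame mean-height series.
#' @param min_overlap Minimum admissible overlap length in frames
#'   (default 60).
#' @param max_lag Search half-range (default: half the shorter series).
#' @return Integer lag; ties are broken towards the smallest `|lag|`, then
#'   the smaller lag.
#' @export
align_colony_time <- function(a, b, min_overlap = 60L, max_lag = NULL) {
  la <- length(a); lb <- length(b)
  if (min(la, lb) < 2L * min_overlap)
    stop("series too short: need at least 2 * min_overlap frames")
  if (is.null(max_lag)) max_lag <- floor(min(la, lb) / 2)
  lags <- seq(-max_lag, max_lag)
  mse <- vapply(lags, function(k) {
    if (k >= 0) {
      n <- min(la, lb - k)
      if (n < min_overlap) return(NA_real_)
      mean((a[seq_len(n)] - b[seq_len(n) + k])^2, na.rm = TRUE)
    } else {
      n <- min(la + k, lb)
      if (n < min_overlap) return(NA_real_)
      mean((a[seq_len(n) - k] - b[seq_len(n)])^2, na.rm = TRUE)
    }
  }, numeric(1))
  if (all(is.na(mse))) stop("no admissible lag with sufficient overlap")
  best <- min(mse, na.rm = TRUE)
  cand <- lags[!is.na(mse) & mse <= best + 1e-12]
  cand[order(abs(cand), cand)][1]
}

#' Hexagonal-prism cell radius from nuclear volume and height
#'
#' Models each cell as a right hexagonal prism of volume
#' `Volume = 3 a s h` (apothem `a`, side `s`, height `h`), with cell volume
#' derived from nuclear volume via the nuclear-to-cytoplasmic ratio. With
#' `a = s sqrt(3)/2`, the in-plane radius is `radius = s sqrt(3)/2`; at
#' fixed volume it scales as `1/sqrt(h)`.
#'
#' @param nuclear_volume Nuclear volume (um^3).
#' @param height Cell (nuclear) height (um).
#' @param nc_ratio Nuclear-to-cytoplasmic volume ratio (default 0.28).
#' @return Radius in um.
#' @export
hex_prism_radius <- function(nuclear_volume, height, nc_ratio = 0.28) {
  if (any(nuclear_volume <= 0) || any(height <= 0) || nc_ratio <= 0)
    stop("all inputs must be positive")
  cell_volume <- nuclear_volume / nc_ratio
  s <- sqrt(2 * cell_volume / (3 * sqrt(3) * height))
  s * sqrt(3) / 2
}

#' Gaussian-weighted moving average of cell radii binned by height
#'
#' Smooths approximate cell radii over nuclear height for comparison with
#' the hexagonal-prism model curve.
#'
#' @param height Nuclear heights (um).
#' @param radius Approximate cell radii (um).
#' @param bandwidth Gaussian kernel SD in um of height (default 0.5).
#' @param grid Heights at which to evaluate (default: 50 points over the
#'   observed range).
#' @return `data.table` with `height` and `radius_smooth`.
#' @export
smooth_radius_by_height <- function(height, radius, bandwidth = 0.5,
                                    grid = NULL) {
  ok <- !is.na(height) & !is.na(radius)
  height <- height[ok]; radius <- radius[ok]
  if (is.null(grid))
    grid <- seq(min(height), max(height), length.out = 50)
  sm <- vapply(grid, function(g) {
    w <- dnorm(height, g, bandwidth)
    if (sum(w) < 1e-12) return(NA_real_)
    sum(w * radius) / sum(w)
  }, numeric(1))
  data.table::data.table(height = grid, radius_smooth = sm)
}

#' Neighbourhood-averaged transient growth rate
#'
#' For each nucleus, the mean of the transient growth rates of all other
#' nuclei whose centroids lie within `radius_um` (default 90 um). The focal
#' nucleus is excluded; the result is missing when no neighbour with a
#' valid rate is in range.
#'
#' @param x,y Centroid coordinates (um) at one frame.
#' @param rates Transient growth rates (um^3/h, NA allowed).
#' @param radius_um Neighbourhood radius (default 90).
#' @return Numeric vector of neighbourhood means.
#' @export
neighborhood_mean_rate <- function(x, y, rates, radius_um = 90) {
  n <- length(x)
  stopifnot(length(y) == n, length(rates) == n)
  inb <- outer(x, x, `-`)^2 + outer(y, y, `-`)^2 <= radius_um^2
  diag(inb) <- FALSE
  inb[, is.na(rates)] <- FALSE
  counts <- rowSums(inb)
  sums <- as.numeric(inb %*% ifelse(is.na(rates), 0, rates))
  out <- sums / counts
  out[counts == 0] <- NA_real_
  out
}
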