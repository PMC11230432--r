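# colony context: adjacency, density, depth, radial slope, colony-time
# alignment, hexagonal-prism model, neighbourhood rates

test_that("a triangle has 3 edges, all nodes boundary", {
  g <- voronoi_adjacency(c(0, 10, 5), c(0, 0, 8))
  expect_equal(nrow(g$edges), 3)
  expect_true(all(g$boundary))
  dep <- colony_depth(g)
  expect_true(all(dep$normalized_depth == 1)) # all-boundary convention
})

test_that("degenerate geometry errors", {
  expect_error(voronoi_adjacency(c(0, 1), c(0, 0)), "at least 3")
  expect_error(voronoi_adjacency(c(0, 1, 2, 3), c(0, 1, 2, 3)), "collinear")
})

test_that("adjacency equals brute-force Delaunay on random sets", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    g <- voronoi_adjacency(x, y)
    expect_equal(edges_as_set(g$edges),
                 edges_as_set(bf_delaunay_edges(x, y)))
  }
})

test_that("perturbed lattices have the expected interior degree", {
  set.seed(32)
  gr <- expand.grid(ix = 1:5, iy = 1:5)
  x <- gr$ix * 10 + rnorm(25, 0, 0.5)
  y <- gr$iy * 10 + rnorm(25, 0, 0.5)
  g <- voronoi_adjacency(x, y)
  interior <- which(gr$ix %in% 2:4 & gr$iy %in% 2:4)
  degs <- lengths(g$neighbors)[interior]
  expect_true(all(degs >= 4 & degs <= 8)) # 6 +/- 2
  expect_equal(edges_as_set(g$edges), edges_as_set(bf_delaunay_edges(x, y)))

  # perturbed hexagonal lattice: interior degree exactly 6
  hx <- expand.grid(i = 0:6, j = 0:6)
  px <- hx$i * 10 + (hx$j %% 2) * 5 + rnorm(49, 0, 0.15)
  py <- hx$j * 10 * sqrt(3) / 2 + rnorm(49, 0, 0.15)
  gh <- voronoi_adjacency(px, py)
  inner <- which(hx$i %in% 2:4 & hx$j %in% 2:4)
  expect_true(all(lengths(gh$neighbors)[inner] == 6))
})

test_that("local density and cell radius follow their closed forms", {
  # neighbors at 8 and 12 um -> mean 10 -> density 0.01
  g <- list(mean_nbr_dist = c(10, NA), density = c(0.01, NA))
  expect_equal(local_density(g, 1), 0.01)
  expect_true(is.na(local_density(g, 2)))
  expect_equal(approx_cell_radius(g, 1), 5)

  # hexagonal lattice spacing L: interior density = 1/L^2, radius = L/2
  hx <- expand.grid(i = 0:6, j = 0:6)
  px <- hx$i * 10 + (hx$j %% 2) * 5
  py <- hx$j * 10 * sqrt(3) / 2 + 1e-6 * rnorm(49)
  gh <- voronoi_adjacency(px, py)
  center <- which.min((px - mean(px))^2 + (py - mean(py))^2)
  expect_equal(local_density(gh, center), 0.01, tolerance = 1e-6)
  # spacing 16 -> radius 8
  g16 <- voronoi_adjacency(px * 1.6, py * 1.6)
  expect_equal(approx_cell_radius(g16, center), 8, tolerance = 1e-6)
  # identity: density == 1/(2 radius)^2
  expect_equal(local_density(gh), 1 / (2 * approx_cell_radius(gh))^2)
})

test_that("colony depth does a hand-checkable BFS on the 5x5 grid", {
  set.seed(2)
  gr <- expand.grid(ix = 1:5, iy = 1:5)
  x <- gr$ix * 10 + rnorm(25, 0, 0.5)
  y <- gr$iy * 10 + rnorm(25, 0, 0.5)
  dep <- colony_depth(voronoi_adjacency(x, y))
  perim <- gr$ix %in% c(1, 5) | gr$iy %in% c(1, 5)
  ring <- !perim & (gr$ix %in% c(2, 4) | gr$iy %in% c(2, 4))
  center <- gr$ix == 3 & gr$iy == 3
  expect_true(all(dep$depth[perim] == 1))
  expect_true(all(dep$depth[ring] == 2))
  expect_equal(dep$depth[center], 3)
  expect_equal(dep$normalized_depth[center], 0)
  expect_true(all(dep$normalized_depth[ring] == 0.5))
  expect_true(all(dep$normalized_depth[perim] == 1))
})

test_that("depth is invariant to relabeling and rigid motion", {
  set.seed(33)
  x <- runif(20, 0, 50); y <- runif(20, 0, 50)
  d1 <- colony_depth(voronoi_adjacency(x, y))$depth
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 100
  yr <- sin(th) * x + cos(th) * y - 40
  d2 <- colony_depth(voronoi_adjacency(xr, yr))$depth
  expect_equal(d2, d1)
  perm <- sample(20)
  d3 <- colony_depth(voronoi_adjacency(x[perm], y[perm]))$depth
  expect_equal(d3, d1[perm])
})

test_that("radial height slope has the documented sign convention", {
  dn <- runif(30)
  up <- radial_height_slope(5 + 2 * dn, dn)
  expect_equal(up$slope, 2, tolerance = 1e-9)
  expect_equal(up$pearson_r, 1, tolerance = 1e-9)
  down <- radial_height_slope(10 - 3 * dn, dn) # taller center
  expect_equal(down$slope, -3, tolerance = 1e-9)
  expect_equal(down$pearson_r, -1, tolerance = 1e-9)
  flat <- radial_height_slope(rep(7, 30), dn)
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  expect_true(is.na(flat$pearson_r))
  expect_true(is.na(radial_height_slope(5 + 2 * dn, rep(0.5, 30))$slope))
})

test_that("colony-time alignment recovers injected lags", {
  a <- sin(seq(0, 8, length.out = 400)) + seq(0, 1, length.out = 400)
  expect_equal(align_colony_time(a, a), 0)
  for (k in c(3, 17, 60)) {
    b <- c(rep(a[1], k), a)[seq_along(a)]
    expect_equal(align_colony_time(a, b), k)
  }
  bneg <- a[-(1:9)]
  expect_equal(align_colony_time(a, bneg), -9)
  # constant series: all lags tie, smallest |lag| wins
  expect_equal(align_colony_time(rep(1, 300), rep(1, 300)), 0)
  expect_error(align_colony_time(a[1:50], a[1:50]), "too short")
})

test_that("hex-prism radius matches its closed form and scaling law", {
  r <- hex_prism_radius(630, 10)
  expect_equal(r, 8.059, tolerance = 1e-3)
  # Volume = 3*a*s*h reconstructs to 1e-9
  s <- r / (sqrt(3) / 2); a <- s * sqrt(3) / 2
  expect_equal(3 * a * s * 10, 630 / 0.28, tolerance = 1e-9)
  # doubling h divides the radius by sqrt(2)
  expect_equal(hex_prism_radius(630, 20), r / sqrt(2), tolerance = 1e-12)
  hh <- seq(2, 20, by = 0.5)
  expect_true(all(diff(hex_prism_radius(630, hh)) < 0))
  expect_error(hex_prism_radius(-1, 10), "positive")
})

test_that("packed-lattice radii agree with the hex-prism model", {
  # build a packed colony the model assumes: hexagonal patches of
  # different spacing, heights set by volume conservation for cells of
  # fixed nuclear volume 630 um^3 (cell volume 2250)
  set.seed(34)
  mk_patch <- function(L, x0) {
    hx <- expand.grid(i = 0:8, j = 0:8)
    px <- hx$i * L + (hx$j %% 2) * L / 2 + x0 + rnorm(81, 0, 0.02 * L)
    py <- hx$j * L * sqrt(3) / 2 + rnorm(81, 0, 0.02 * L)
    h <- (630 / 0.28) / (sqrt(3) / 2 * L^2)
    list(x = px, y = py, h = h,
         interior = hx$i %in% 2:6 & hx$j %in% 2:6)
  }
  spacings <- c(12, 14, 16, 18)
  rows <- lapply(seq_along(spacings), function(k) {
    p <- mk_patch(spacings[k], x0 = k * 400)
    g <- voronoi_adjacency(p$x, p$y)
    data.frame(height = p$h, radius = approx_cell_radius(g)[p$interior])
  })
  dat <- do.call(rbind, rows)
  sm <- smooth_radius_by_height(dat$height, dat$radius, bandwidth = 0.5,
                                grid = unique(dat$height))
  model <- hex_prism_radius(630, sm$height)
  expect_true(all(abs(sm$radius_smooth - model) / model < 0.1))
})

test_that("neighbourhood mean rate excludes self and empty neighbourhoods", {
  r <- neighborhood_mean_rate(c(0, 50), c(0, 0), c(20, 40))
  expect_equal(r, c(40, 20))
  far <- neighborhood_mean_rate(c(0, 200), c(0, 0), c(20, 40))
  expect_true(all(is.na(far)))
})

test_that("neighbourhood coupling: local mean beats the colony mean", {
  # with the shared rate field on, a nucleus' transient rate correlates
  # more strongly with its 90 um neighbourhood mean than with the
  # colony-wide mean (pooled over nuclei and frames)
  fix <- population_fixture()
  tab <- table_from_trajectories(fix$trajs)
  rates <- data.table::rbindlist(lapply(fix$trajs, function(t) {
    rs <- transient_growth_rate(t)
    data.table::data.table(track_id = t$track_id, frame = rs$frame,
                           rate = rs$rate)
  }))
  tab <- merge(tab, rates, by = c("track_id", "frame"))
  own <- c(); nbr <- c(); colm <- c()
  for (f in seq(100, 460, by = 10)) {
    g <- tab[frame == f & !is.na(rate) & !is.na(x)]
    if (nrow(g) < 20) next
    nm <- neighborhood_mean_rate(g$x, g$y, g$rate, 90)
    cm <- (sum(g$rate) - g$rate) / (nrow(g) - 1)
    ok <- !is.na(nm)
    own <- c(own, g$rate[ok]); nbr <- c(nbr, nm[ok])
    colm <- c(colm, cm[ok])
  }
  expect_gt(length(own), 2000)
  r_nbr <- cor(own, nbr)
  r_col <- cor(own, colm)
  expect_gt(r_nbr, 0.05)
  expect_gt(r_nbr, r_col)
})
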