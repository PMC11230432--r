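# Shared fixtures and independent brute-force oracles. Oracles are written
# from first principles (exhaustive enumeration, closed forms) and never
# call the implementation paths they check.

# build a minimal single-track trajectory from a volume series
mk_traj <- function(volume, frame0 = 0L, formation = frame0,
                    breakdown = NA_integer_, x = 0, y = 0, height = 5,
                    fov_edge = FALSE, track_id = 1L) {
  n <- length(volume)
  d <- data.frame(frame = frame0 + seq_len(n) - 1L, time_min = NA_real_,
                  x = rep_len(x, n), y = rep_len(y, n), z = 0,
                  volume = volume, height = rep_len(height, n),
                  aspect_ratio_xy = 1.2, fov_edge = rep_len(fov_edge, n),
                  is_tp_outlier = FALSE)
  trajectory(track_id, d, formation_frame = formation,
             breakdown_frame = if (is.na(breakdown)) frame0 + n - 1L
                               else breakdown)
}

# canonical feature-table row block for table-level tests
mk_feature_table <- function(track_ids, frames, volume = 500) {
  data.frame(track_id = track_ids, frame = frames,
             time_min = frames * 5, x = as.numeric(track_ids),
             y = 0, z = 0, volume = rep_len(volume, length(frames)),
             height = 5, aspect_ratio_xy = 1.2, fov_edge = FALSE,
             is_tp_outlier = FALSE)
}

# ---- oracle: exhaustive minimum-cost matching with birth/death ----
# enumerates every partial matching between rows and columns of `cost`
# (Inf = inadmissible); unmatched nodes on either side cost `bd` each
bf_min_matching_cost <- function(cost, bd) {
  na <- nrow(cost); nb <- ncol(cost)
  best <- Inf
  rec <- function(i, used_cols, acc) {
    if (acc >= best) return()
    if (i > na) {
      total <- acc + bd * (nb - length(used_cols))
      if (total < best) best <<- total
      return()
    }
    rec(i + 1L, used_cols, acc + bd) # row i unmatched
    for (j in seq_len(nb)) {
      if (j %in% used_cols || !is.finite(cost[i, j])) next
      rec(i + 1L, c(used_cols, j), acc + cost[i, j])
    }
  }
  rec(1L, integer(0), 0)
  best
}

# total cost implied by a set of links returned by link_frames()
links_total_cost <- function(links, a, b, params) {
  bd <- params$birth_death_cost
  sum(links$cost) + bd * (nrow(a) - nrow(links)) + bd * (nrow(b) - nrow(links))
}

# ---- oracle: brute-force Delaunay edges by the empty-circumcircle test ----
bf_delaunay_edges <- function(x, y) {
  n <- length(x)
  in_circ <- function(ax, ay, bx, by, cx, cy, px, py) {
    o <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d <- det(matrix(c(ax - px, ay - py, (ax - px)^2 + (ay - py)^2,
                      bx - px, by - py, (bx - px)^2 + (by - py)^2,
                      cx - px, cy - py, (cx - px)^2 + (cy - py)^2),
                    3, 3, byrow = TRUE))
    if (o < 0) d <- -d
    d > 1e-9
  }
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    o <- (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
    if (abs(o) < 1e-12) next
    empty <- TRUE
    for (p in seq_len(n)) {
      if (p %in% c(i, j, k)) next
      if (in_circ(x[i], y[i], x[j], y[j], x[k], y[k], x[p], y[p])) {
        empty <- FALSE; break
      }
    }
    if (empty) edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  edges <- t(apply(edges, 1, sort))
  unique(as.data.frame(edges))
}

edges_as_set <- function(e) {
  e <- as.matrix(e)
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-"))
}

# ---- oracle: rolling median with the documented asymmetric padding ----
bf_rolling_median <- function(v, window) {
  half <- (window - 1) %/% 2
  obs <- v[!is.na(v)]
  vp <- c(rep(obs[1], half), v, rep(median(tail(obs, 3)), half))
  sapply(seq_along(v), function(i) median(vp[i:(i + window - 1)], na.rm = TRUE))
}

# ---- oracle: exhaustive two-segment breakpoint least squares ----
bf_two_segment_breakpoint <- function(t, v) {
  n <- length(t)
  best_b <- NA; best_sse <- Inf
  for (b in 3:(n - 2)) {
    f1 <- lm(v[1:b] ~ t[1:b])
    f2 <- lm(v[b:n] ~ t[b:n])
    sse <- sum(resid(f1)^2) + sum(resid(f2)^2)
    if (sse < best_sse) { best_sse <- sse; best_b <- b }
  }
  t[best_b]
}

# ---- shared population fixture (built once per test run) ----
# a colony large enough for population and lineage statistics: ~550
# completed generations, ~200 sister pairs. Seed fixed; downstream stages
# (transitions, summaries, pairs) cached alongside.
.ng_fixture_env <- new.env(parent = emptyenv())

population_fixture <- function() {
  if (!is.null(.ng_fixture_env$pop)) return(.ng_fixture_env$pop)
  sim <- simulate_colony(sim_config(n_founders = 120, n_frames = 480,
                                    seed = 11))
  trajs <- trajectories_from_table(sim$features, lineage = sim$lineage)
  trajs <- flag_fov_edge(trajs)
  trajs <- flag_volume_outliers_all(trajs)
  trajs <- detect_transitions(trajs)
  full <- select_full_interphase(trajs)
  summaries <- growth_summaries(full)
  pairs <- find_pairs(sim$lineage, summaries)
  meta <- control_metadata(full, summaries)
  fix <- list(sim = sim, trajs = trajs, full = full, summaries = summaries,
              pairs = pairs, meta = meta)
  .ng_fixture_env$pop <- fix
  fix
}

# small colony for pipeline smoke tests
small_sim <- function(seed = 3) {
  key <- paste0("small", seed)
  if (!is.null(.ng_fixture_env[[key]])) return(.ng_fixture_env[[key]])
  sim <- simulate_colony(sim_config(n_founders = 10, n_frames = 240,
                                    seed = seed))
  .ng_fixture_env[[key]] <- sim
  sim
}
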