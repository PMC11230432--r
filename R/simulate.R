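# Synthetic colony simulator. Generates colonies of growing, dividing nuclei
# with the statistical structure the downstream analysis assumes: biphasic
# volume trajectories (rapid post-mitotic expansion, then slow power-law
# growth), adder-like size control, duration-size compensation, division
# retention of ~95.9% of the mother's ending volume, a radial height gradient
# whose slope drifts in time, neighbourhood-correlated transient rates, and
# 0.64% multiplicative volume measurement noise.

#' Simulator configuration
#'
#' Defaults are the population parameters of the study: expansion duration
#' 38 +/- 10 min, growth duration 14.9 +/- 1.9 h, founder starting volumes
#' 517.9 +/- 54.9 um^3, added-volume CV 0.177, division retention
#' 0.959 +/- 0.042, power-law exponent peaked at 1.15, measurement noise
#' 0.64%. The duration-size slope defaults to the value that yields a
#' duration vs starting-volume correlation of about -0.55 given those
#' spreads.
#'
#' @param n_founders Number of founder nuclei.
#' @param n_frames Number of movie frames.
#' @param frame_interval_min Minutes per frame (default 5).
#' @param expansion_mean_min,expansion_sd_min Rapid-expansion duration (min).
#' @param growth_mean_h,growth_sd_h Growth-phase duration (hours).
#' @param duration_size_corr Target correlation between growth duration and
#'   starting volume (default -0.55); the slope in min per um^3 is derived
#'   from this and the configured spreads.
#' @param start_volume_mean,start_volume_sd Founder starting volumes (um^3).
#' @param added_volume_mean Mean added volume (um^3, default equal to the
#'   mean starting volume so the population doubles).
#' @param added_volume_cv Coefficient of variation of added volume.
#' @param retention_mean,retention_sd Fraction of the mother's ending volume
#'   retained by the two daughters combined.
#' @param asymmetry_sd SD of the daughter volume fraction about 0.5.
#' @param duration_latent_sd_min SD (minutes) of the heritable duration
#'   component: each division draws one latent that both daughters share,
#'   partially inherited from the mother's latent. This is what makes
#'   growth duration an inherited feature beyond the duration-size
#'   compensation (volume-matched control pairs share the compensation but
#'   not the latent). Default 45.
#' @param duration_latent_inherit Mother-to-daughter latent correlation
#'   (default 0.5).
#' @param alpha_mean,alpha_sd Power-law exponent distribution (truncated to
#'   `[0.5, 2]`).
#' @param measurement_noise_frac Multiplicative volume noise SD per frame.
#' @param coupling_weight Amplitude of the shared smooth spatiotemporal field
#'   multiplying instantaneous growth rates (0 disables coupling).
#' @param coupling_length_um,coupling_time_h Field correlation scales.
#' @param founder_spacing_um Founder lattice spacing.
#' @param motility_sd_um Per-frame centroid jitter SD.
#' @param division_push_um Radial displacement applied to neighbours of a
#'   dividing nucleus (decays with distance; a density-fluctuation knob).
#' @param expansion_depth_fraction Post-mitotic volume as a fraction of the
#'   starting volume (the expansion rises from this fraction to 1).
#' @param height_base_um Mean nuclear height at the colony centre.
#' @param height_gradient_start,height_gradient_end Radial height slope
#'   (um per unit normalized radius) at the first and last frame; the slope
#'   drifts linearly between them, producing the sign reversal seen in
#'   developing colonies.
#' @param height_noise_um Per-record height noise SD.
#' @param fov_half_um Half-width of the square field of view; records beyond
#'   it are flagged `fov_edge`.
#' @param founder_stagger_frames Founder formation frames are drawn uniformly
#'   from `[-founder_stagger_frames, 0]` to desynchronise the population.
#' @param long_duration_fraction Fraction of nuclei given a 22-37 h growth
#'   duration (an outlier subpopulation; 0 by default, switch on to exercise
#'   the long-duration filter).
#' @param seed Integer seed.
#' @return A list of class `ng_sim_config`.
#' @export
sim_config <- function(n_founders = 40,
                       n_frames = 450,
                       frame_interval_min = 5,
                       expansion_mean_min = 38,
                       expansion_sd_min = 10,
                       growth_mean_h = 14.9,
                       growth_sd_h = 1.9,
                       duration_size_corr = -0.55,
                       start_volume_mean = 517.9,
                       start_volume_sd = 54.9,
                       added_volume_mean = 517.9,
                       added_volume_cv = 0.177,
                       retention_mean = 0.959,
                       retention_sd = 0.042,
                       asymmetry_sd = 0.015,
                       duration_latent_sd_min = 45,
                       duration_latent_inherit = 0.5,
                       alpha_mean = 1.15,
                       alpha_sd = 0.2,
                       measurement_noise_frac = 0.0064,
                       coupling_weight = 0.3,
                       coupling_length_um = 90,
                       coupling_time_h = 4,
                       founder_spacing_um = 18,
                       motility_sd_um = 0.25,
                       division_push_um = 1.5,
                       expansion_depth_fraction = 0.72,
                       height_base_um = 7,
                       height_gradient_start = -2.5,
                       height_gradient_end = 1.5,
                       height_noise_um = 0.4,
                       fov_half_um = 250,
                       founder_stagger_frames = 180,
                       long_duration_fraction = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_founders >= 1, n_frames >= 2, frame_interval_min > 0,
    expansion_mean_min > 0, expansion_sd_min > 0,
    growth_mean_h > 0, growth_sd_h > 0,
    start_volume_mean > 0, start_volume_sd > 0,
    added_volume_mean > 0, added_volume_cv > 0,
    retention_mean > 0, retention_mean <= 1, retention_sd >= 0,
    asymmetry_sd >= 0, asymmetry_sd < 0.5,
    alpha_mean > 0, alpha_sd >= 0,
    measurement_noise_frac >= 0, coupling_weight >= 0,
    expansion_depth_fraction > 0, expansion_depth_fraction < 1,
    long_duration_fraction >= 0, long_duration_fraction < 1
  )
  structure(cfg, class = "ng_sim_config")
}

#' Split a mother's ending volume between two daughters
#'
#' The daughters' combined starting volume is `retention` times the mother's
#' ending volume (study average 95.9 +/- 4.2%), and daughter 1 receives the
#' fraction `asymmetry_fraction` of that combined volume.
#'
#' @param mother_end_volume Mother's ending volume (um^3), > 0.
#' @param retention Fraction of the mother's volume retained, in (0, 1.2]
#'   (values slightly above 1 occur when the nucleus grows between the
#'   mother's breakdown and the daughters' transitions).
#' @param asymmetry_fraction Daughter 1's share of the combined volume,
#'   in (0, 1); 0.5 is a symmetric division.
#' @return Numeric vector `c(daughter1, daughter2)` of starting volumes.
#' @export
divide_nucleus <- function(mother_end_volume, retention, asymmetry_fraction) {
  if (!is.numeric(mother_end_volume) || mother_end_volume <= 0)
    stop("mother_end_volume must be positive")
  if (retention <= 0 || retention > 1.2)
    stop("retention must be in (0, 1.2]")
  if (asymmetry_fraction <= 0 || asymmetry_fraction >= 1)
    stop("asymmetry_fraction must be in (0, 1)")
  combined <- retention * mother_end_volume
  c(asymmetry_fraction * combined, (1 - asymmetry_fraction) * combined)
}

# truncated-normal draw: redraw until all values exceed `lower`
rnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated-normal rejection failed to converge")
  }
  x
}

#' Generate one biphasic nuclear volume trajectory
#'
#' The volume rises steeply from `depth_fraction * start_volume` to
#' `start_volume` over the expansion phase (a saturating exponential), then
#' follows the power law `V(t) = start_volume + r * t^alpha` with `r` chosen
#' so that the volume at the end of growth equals
#' `start_volume + added_volume`. Multiplicative measurement noise of SD
#' `noise_frac` is applied per frame.
#'
#' @param start_volume Volume at the expansion-to-growth transition (um^3).
#' @param expansion_min Expansion duration in minutes.
#' @param growth_duration_h Growth duration in hours.
#' @param alpha Power-law exponent.
#' @param dt_min Frame interval in minutes (must not exceed `expansion_min`,
#'   otherwise the transition is unresolvable).
#' @param noise_frac Multiplicative noise SD (0 for noise-free).
#' @param added_volume Volume added during growth; if `NULL`, drawn from a
#'   truncated normal with mean `start_volume` and CV 0.177 (the adder rule).
#' @param depth_fraction Post-mitotic volume fraction (default 0.72).
#' @return List with `volume` (per-frame, frame 0 = formation), `time_min`,
#'   `transition_index` (1-based index of the first growth-phase frame) and
#'   the realised `added_volume`.
#' @export
make_biphasic_trajectory <- function(start_volume, expansion_min,
                                     growth_duration_h, alpha,
                                     dt_min = 5, noise_frac = 0,
                                     added_volume = NULL,
                                     depth_fraction = 0.72) {
  stopifnot(start_volume > 0, growth_duration_h > 0, alpha > 0, dt_min > 0)
  if (dt_min > expansion_min)
    stop("frame interval exceeds expansion duration: transition unresolvable")
  if (is.null(added_volume))
    added_volume <- rnorm_trunc(1, start_volume, 0.177 * start_volume)
  tg_min <- growth_duration_h * 60
  tt <- seq(0, expansion_min + tg_min, by = dt_min)
  v <- biphasic_volume(tt, start_volume, expansion_min, tg_min, alpha,
                       added_volume, depth_fraction)
  if (noise_frac > 0) v <- v * (1 + rnorm(length(v), 0, noise_frac))
  list(volume = v, time_min = tt,
       transition_index = which(tt >= expansion_min)[1],
       added_volume = added_volume)
}

# closed-form biphasic volume at times tt (minutes since formation): a
# linear ramp from depth*v0 to v0 over the expansion (rapid import-driven
# swelling, still steep when growth takes over, giving the abrupt slowdown
# seen in single-nucleus trajectories), then the power-law growth segment
biphasic_volume <- function(tt, v0, te_min, tg_min, alpha, dv, depth = 0.72) {
  r <- dv / (tg_min / 60)^alpha
  ifelse(tt < te_min,
         v0 - (1 - depth) * v0 * (1 - tt / te_min),
         v0 + r * ((tt - te_min) / 60)^alpha)
}

#' Simulate a colony of growing, dividing nuclei
#'
#' Event-driven simulation: each nucleus forms, expands, grows (with its
#' instantaneous rate modulated by a shared smooth spatiotemporal field when
#' `coupling_weight > 0`), breaks down and divides; daughters start new
#' tracks (mitosis is never tracked through). Positions follow a random walk
#' from the founder lattice, with a local outward push at each division.
#' Heights follow a radial gradient whose slope drifts linearly over the
#' movie.
#'
#' @param config A [sim_config()].
#' @return List with `features` (feature table, one row per nucleus per
#'   frame), `lineage` (`track_id, parent_id, family_id`), and `truth`
#'   (per-track ground truth: true formation/transition/breakdown frames,
#'   alpha, starting/ending/added volume, retention, asymmetry fraction).
#' @export
simulate_colony <- function(config = sim_config()) {
  stopifnot(inherits(config, "ng_sim_config"))
  cf <- config
  set.seed(cf$seed)
  dt <- cf$frame_interval_min

  # derived duration-size slope (min per um^3) hitting the target correlation;
  # the residual splits into a heritable latent (shared by sisters) and
  # individual noise so the total duration SD stays at growth_sd_h
  sd_t_min <- cf$growth_sd_h * 60
  slope <- cf$duration_size_corr * sd_t_min / cf$start_volume_sd
  tau <- min(cf$duration_latent_sd_min, 0.9 * sd_t_min)
  resid_var <- sd_t_min^2 - (slope * cf$start_volume_sd)^2 - tau^2
  resid_sd <- sqrt(max(resid_var, 1e-8))

  field <- if (cf$coupling_weight > 0) make_coupling_field(cf) else NULL

  founders_xy <- hex_lattice(cf$n_founders, cf$founder_spacing_um)
  founders_xy <- founders_xy +
    matrix(rnorm(2 * cf$n_founders, 0, 0.15 * cf$founder_spacing_um),
           ncol = 2)

  # per-track state queue, processed in order of formation
  queue <- vector("list", cf$n_founders)
  for (i in seq_len(cf$n_founders)) {
    queue[[i]] <- list(
      track_id = i, parent_id = NA_integer_, family_id = i,
      formation_frame = -sample.int(cf$founder_stagger_frames + 1L, 1L) + 1L,
      start_volume = rnorm_trunc(1, cf$start_volume_mean, cf$start_volume_sd,
                                 lower = 50),
      dur_latent = rnorm(1, 0, tau),
      pos = founders_xy[i, ])
  }
  next_id <- cf$n_founders + 1L
  head_i <- 1L
  tracks <- list()
  truth_rows <- list()
  divisions <- list()

  while (head_i <= length(queue)) {
    st <- queue[[head_i]]
    head_i <- head_i + 1L
    tr <- grow_one_track(st, cf, dt, slope, resid_sd, field)
    truth_rows[[length(truth_rows) + 1L]] <- tr$truth
    if (!is.null(tr$records)) tracks[[length(tracks) + 1L]] <- tr$records
    if (tr$divides) {
      divisions[[length(divisions) + 1L]] <-
        list(frame = tr$truth$breakdown_frame, pos = tr$end_pos)
      dv <- divide_nucleus(tr$truth$end_volume, tr$retention, tr$asym)
      ang <- runif(1, 0, 2 * pi)
      off <- 4 * c(cos(ang), sin(ang))
      rho <- cf$duration_latent_inherit
      kid_latent <- rho * st$dur_latent + sqrt(max(1 - rho^2, 0)) *
        rnorm(1, 0, tau)
      for (d in 1:2) {
        queue[[length(queue) + 1L]] <- list(
          track_id = next_id, parent_id = st$track_id,
          family_id = st$family_id,
          formation_frame = tr$truth$breakdown_frame + 2L,
          start_volume = dv[d],
          dur_latent = kid_latent,
          pos = tr$end_pos + if (d == 1) off else -off)
        next_id <- next_id + 1L
      }
    }
  }

  feat <- data.table::rbindlist(tracks, use.names = TRUE)
  truth <- data.table::rbindlist(truth_rows, use.names = TRUE)

  # local outward push around each division (density fluctuations)
  if (cf$division_push_um > 0 && length(divisions) && nrow(feat)) {
    for (ev in divisions) {
      if (ev$frame < 0 || ev$frame >= cf$n_frames) next
      sel <- feat$frame >= ev$frame
      if (!any(sel)) next
      dx <- feat$x[sel] - ev$pos[1]
      dy <- feat$y[sel] - ev$pos[2]
      dd <- sqrt(dx^2 + dy^2)
      w <- cf$division_push_um * exp(-dd / 15)
      nz <- dd > 1e-9
      feat$x[sel][nz] <- feat$x[sel][nz] + w[nz] * dx[nz] / dd[nz]
      feat$y[sel][nz] <- feat$y[sel][nz] + w[nz] * dy[nz] / dd[nz]
    }
  }

  # heights: radial gradient with a linearly drifting slope
  feat[, z := 0]
  grad <- cf$height_gradient_start +
    (cf$height_gradient_end - cf$height_gradient_start) *
    feat$frame / max(cf$n_frames - 1, 1)
  feat[, height := {
    cx <- mean(x); cy <- mean(y)
    rr <- sqrt((x - cx)^2 + (y - cy)^2)
    rho <- if (max(rr) > 0) rr / max(rr) else rr
    cf$height_base_um + grad[.I] * rho + rnorm(.N, 0, cf$height_noise_um)
  }, by = frame]
  feat[, height := pmax(height, 1)]

  feat[, aspect_ratio_xy := rnorm_trunc(.N, 1.3, 0.15, lower = 1)]
  if (cf$measurement_noise_frac > 0)
    feat[, volume := volume * (1 + rnorm(.N, 0, cf$measurement_noise_frac))]
  feat[, fov_edge := pmax(abs(x), abs(y)) > cf$fov_half_um]
  feat[, is_tp_outlier := FALSE]
  feat[, time_min := frame * dt]
  # lifecycle labels: only events inside the movie are observed
  feat[, formation_frame := {
    f <- truth$formation_frame[match(track_id, truth$track_id)]
    ifelse(f >= 0, f, NA_integer_)
  }]
  feat[, breakdown_frame := {
    b <- truth$breakdown_frame[match(track_id, truth$track_id)]
    ifelse(b < cf$n_frames, b, NA_integer_)
  }]
  data.table::setcolorder(feat, c("track_id", "frame", "time_min", "x", "y",
                                  "z", "volume", "height", "aspect_ratio_xy",
                                  "fov_edge", "is_tp_outlier",
                                  "formation_frame", "breakdown_frame"))
  data.table::setorder(feat, track_id, frame)

  lineage <- truth[, list(track_id, parent_id, family_id)]
  list(features = feat[], lineage = lineage[], truth = truth[])
}

# simulate one track from its queued birth state; returns records clipped to
# the movie plus the ground-truth row
grow_one_track <- function(st, cf, dt, slope, resid_sd, field) {
  te_min <- rnorm_trunc(1, cf$expansion_mean_min, cf$expansion_sd_min,
                        lower = dt + 1e-9)
  tg_min <- cf$growth_mean_h * 60 +
    slope * (st$start_volume - cf$start_volume_mean) + st$dur_latent +
    rnorm(1, 0, resid_sd)
  tg_min <- max(tg_min, 240)
  if (cf$long_duration_fraction > 0 && runif(1) < cf$long_duration_fraction)
    tg_min <- runif(1, 22, 37) * 60
  alpha <- rnorm_trunc(1, cf$alpha_mean, cf$alpha_sd, lower = 0.5, upper = 2)
  dvol <- rnorm_trunc(1, cf$added_volume_mean,
                      cf$added_volume_cv * cf$added_volume_mean, lower = 25)

  n_life <- floor((te_min + tg_min) / dt)
  frames <- st$formation_frame + 0:n_life
  t_rel <- (0:n_life) * dt
  v_un <- biphasic_volume(t_rel, st$start_volume, te_min, tg_min, alpha,
                          dvol, cf$expansion_depth_fraction)

  # positions: random walk from birth position
  steps <- matrix(rnorm(2 * (n_life + 1), 0, cf$motility_sd_um),
                  ncol = 2)
  steps[1, ] <- 0
  pos <- cbind(st$pos[1] + cumsum(steps[, 1]),
               st$pos[2] + cumsum(steps[, 2]))

  # neighbourhood coupling: modulate growth-phase volume increments by the
  # shared field sampled along the track's path
  v <- v_un
  if (!is.null(field)) {
    g <- lookup_field(field, pos[, 1], pos[, 2], pmax(frames, 0))
    inc <- diff(v_un)
    growing <- t_rel[-1] > te_min
    mod <- inc[growing] * g[-1][growing]
    # renormalise so the track still adds exactly its drawn adder increment:
    # coupling redistributes growth in time, it does not change the total
    if (sum(mod) > 0)
      mod <- mod * sum(inc[growing]) / sum(mod)
    inc[growing] <- mod
    v <- cumsum(c(v_un[1], inc))
  }
  end_volume <- v[length(v)]
  transition_frame <- st$formation_frame +
    (which(t_rel >= te_min)[1] - 1L)
  breakdown_frame <- frames[length(frames)]

  keep <- frames >= 0 & frames < cf$n_frames
  records <- NULL
  if (any(keep)) {
    records <- data.table::data.table(
      track_id = st$track_id, frame = as.integer(frames[keep]),
      x = pos[keep, 1], y = pos[keep, 2], volume = v[keep])
  }
  divides <- breakdown_frame < cf$n_frames - 2L
  ret <- rnorm_trunc(1, cf$retention_mean, cf$retention_sd,
                     lower = 0.5, upper = 1.2)
  asym <- rnorm_trunc(1, 0.5, cf$asymmetry_sd, lower = 0.2, upper = 0.8)
  truth <- data.table::data.table(
    track_id = st$track_id, parent_id = st$parent_id,
    family_id = st$family_id,
    formation_frame = as.integer(st$formation_frame),
    transition_frame = as.integer(transition_frame),
    breakdown_frame = as.integer(breakdown_frame),
    expansion_min = te_min, growth_duration_h = tg_min / 60,
    alpha = alpha, start_volume = st$start_volume,
    end_volume = end_volume, added_volume = end_volume - st$start_volume,
    retention = if (divides) ret else NA_real_,
    asymmetry_fraction = if (divides) asym else NA_real_,
    divided = divides)
  list(records = records, truth = truth, divides = divides,
       end_pos = pos[nrow(pos), ], retention = ret, asym = asym)
}

# compact hexagonal lattice of n points around the origin
hex_lattice <- function(n, spacing) {
  m <- ceiling(sqrt(n)) + 2
  ix <- seq(-m, m)
  pts <- do.call(rbind, lapply(ix, function(row) {
    cbind(ix * spacing + (row %% 2) * spacing / 2,
          row * spacing * sqrt(3) / 2)
  }))
  ord <- order(pts[, 1]^2 + pts[, 2]^2)
  pts[ord[seq_len(n)], , drop = FALSE]
}

# shared multiplicative rate field: iid grid noise smoothed with separable
# Gaussian kernels (length scale coupling_length_um, time scale
# coupling_time_h), standardised, then mapped to 1 + weight * field
make_coupling_field <- function(cf) {
  half <- cf$fov_half_um + 60
  dx_grid <- 30
  xs <- seq(-half, half, by = dx_grid)
  dt_grid_min <- 60
  ts <- seq(0, cf$n_frames * cf$frame_interval_min, by = dt_grid_min)
  arr <- array(rnorm(length(xs)^2 * length(ts)),
               dim = c(length(xs), length(xs), length(ts)))
  gk <- function(sigma_cells) {
    r <- max(1L, ceiling(3 * sigma_cells))
    k <- dnorm(seq(-r, r), 0, sigma_cells)
    k / sum(k)
  }
  ks <- gk(cf$coupling_length_um / dx_grid)
  kt <- gk(cf$coupling_time_h * 60 / dt_grid_min)
  arr <- smooth_dim(arr, ks, 1)
  arr <- smooth_dim(arr, ks, 2)
  arr <- smooth_dim(arr, kt, 3)
  arr <- (arr - mean(arr)) / sd(arr)
  g <- pmax(1 + cf$coupling_weight * arr, 0.1)
  list(g = g, xs = xs, ts = ts,
       frame_min = cf$frame_interval_min)
}

# 1D kernel smoothing along one dimension of a 3D array (replicate padding)
smooth_dim <- function(arr, k, dim) {
  r <- (length(k) - 1L) / 2L
  n <- dim(arr)[dim]
  idx <- function(i) pmin(pmax(i, 1L), n)
  out <- array(0, dim = dim(arr))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    sl <- idx(seq_len(n) + off)
    out <- out + k[j] * switch(dim,
      arr[sl, , , drop = FALSE],
      arr[, sl, , drop = FALSE],
      arr[, , sl, drop = FALSE])
  }
  out
}

lookup_field <- function(field, x, y, frame) {
  ix <- findInterval(x, field$xs, all.inside = TRUE)
  iy <- findInterval(y, field$xs, all.inside = TRUE)
  it <- findInterval(frame * field$frame_min, field$ts, all.inside = TRUE)
  field$g[cbind(ix, iy, it)]
}

#' Generate a bright-field z-stack phantom of a colony
#'
#' A textured disk of the given radius: in-plane texture variance is high
#' inside the colony and negligible outside, and the texture amplitude is
#' minimal at the central focal plane, peaks above and below it, and decays
#' towards the ends of the stack — mimicking a phase object imaged through
#' focus. Used as a recovery oracle for [segment_colony()].
#'
#' @param colony_radius_um Colony radius (um).
#' @param pixel_size_um Pixel size (default 0.271 um/pixel).
#' @param n_z Number of z slices (default 15).
#' @param noise Texture amplitude inside the colony (default 0.45); 0 gives
#'   a textureless stack in which no colony is detectable.
#' @param background_noise Pixel noise outside the colony (default 0.003).
#' @param margin_um Image margin beyond the colony (default 15 um).
#' @return List with `stack` (array `z` x `y` x `x`), `true_area_um2`
#'   (`pi r^2`), and `pixel_size_um`.
#' @export
make_brightfield_phantom <- function(colony_radius_um,
                                     pixel_size_um = 0.271,
                                     n_z = 15,
                                     noise = 0.45,
                                     background_noise = 0.003,
                                     margin_um = 15) {
  stopifnot(colony_radius_um > 0, n_z >= 5)
  half_px <- ceiling((colony_radius_um + margin_um) / pixel_size_um)
  npx <- 2L * half_px + 1L
  cc <- (seq_len(npx) - half_px - 1) * pixel_size_um
  inside <- outer(cc^2, cc^2, `+`) <= colony_radius_um^2
  z_mid <- (n_z + 1) / 2
  dz <- abs(seq_len(n_z) - z_mid)
  d0 <- n_z / 4
  amp <- noise * exp(-(dz - d0)^2 / (2 * (n_z / 8)^2))
  # texture is spatially correlated (sigma ~2 px) like bright-field mottle,
  # so it survives the Sobel filter's smoothing taps
  gk <- local({
    r <- 6L
    k <- dnorm(seq(-r, r), 0, 2)
    k / sum(k)
  })
  stack <- array(0, dim = c(n_z, npx, npx))
  for (zz in seq_len(n_z)) {
    sl <- matrix(1, npx, npx)
    sl <- sl + matrix(rnorm(npx * npx, 0, background_noise), npx, npx)
    if (amp[zz] > 0) {
      tex <- conv2_sep_cpp(matrix(rnorm(npx * npx), npx, npx), gk, gk)
      tex <- tex / sd(tex)
      sl[inside] <- 1 + amp[zz] * tex[inside]
    }
    stack[zz, , ] <- sl
  }
  list(stack = stack, true_area_um2 = pi * colony_radius_um^2,
       pixel_size_um = pixel_size_um)
}
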