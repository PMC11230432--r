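# Per-trajectory growth quantification: detection of the expansion-to-growth
# transition, normalized interphase time, power-law growth-shape fitting,
# transient growth rates and scalar growth summaries.

#' Detect the expansion-to-growth transition of a trajectory
#'
#' The first `window_frames` frames after lamin-shell formation are min-max
#' normalized in time and volume, resampled uniformly in cumulative arc
#' length (increasing sampling density around the bend), and fit to a
#' hyperbola written as the implicit two-line conic
#' \deqn{(y - m_1 x - c_1)(y - m_2 x - c_2) = k, \quad k > 0,}
#' whose asymptotes and center are explicit. The fit is initialised from the
#' best two-segment piecewise-linear fit. The transition is the data
#' abscissa whose hyperbola point lies nearest the center (the asymptote
#' intersection), snapped to the nearest frame with a valid record within
#' two frames.
#'
#' @param traj A trajectory with `formation_frame` set.
#' @param window_frames Frames analysed after formation (default 40).
#' @param arc_points Arc-length resampling density (default 200).
#' @param min_slope_sep Minimum normalized asymptote slope separation for a
#'   valid fit (default 0.15; an exactly linear trajectory fails).
#' @param max_rmse Maximum conic residual RMSE for a valid fit (default 0.05
#'   in normalized units).
#' @return A list of class `ng_transition_fit` with `asymptote1`,
#'   `asymptote2` (slope/intercept pairs), `k`, `center`, `transition_frame`
#'   (NA when invalid), `rmse`, `valid` and `low_confidence` (fewer than
#'   `window_frames` frames were available).
#' @export
detect_transition <- function(traj, window_frames = 40L, arc_points = 200L,
                              min_slope_sep = 0.15, max_rmse = 0.05) {
  failed <- function(reason) {
    structure(list(asymptote1 = c(NA, NA), asymptote2 = c(NA, NA),
                   k = NA_real_, center = c(NA, NA),
                   transition_frame = NA_integer_, rmse = NA_real_,
                   valid = FALSE, low_confidence = TRUE, reason = reason),
              class = "ng_transition_fit")
  }
  if (is.na(traj$formation_frame)) return(failed("no_formation"))
  f0 <- traj$formation_frame
  d <- traj$data
  sel <- d$frame >= f0 & d$frame < f0 + window_frames
  fr <- d$frame[sel]
  v <- clean_volume(traj)[sel]
  low_conf <- sum(sel) < window_frames
  ok <- !is.na(v)
  if (sum(ok) < 8) return(failed("too_few_points"))
  t_rel <- fr - f0

  # normalize to [0,1]^2 and linearly interpolate missing values
  xn <- (t_rel - min(t_rel[ok])) / diff(range(t_rel[ok]))
  rng_v <- range(v[ok])
  if (diff(rng_v) <= 0) return(failed("flat_volume"))
  yn <- (v - rng_v[1]) / diff(rng_v)
  yi <- approx(xn[ok], yn[ok], xout = xn, rule = 2)$y

  # uniform resampling in cumulative arc length
  seg <- sqrt(diff(xn)^2 + diff(yi)^2)
  s <- c(0, cumsum(seg))
  su <- seq(0, s[length(s)], length.out = arc_points)
  xa <- approx(s, xn, xout = su)$y
  ya <- approx(s, yi, xout = su)$y

  # initialise from the best two-segment piecewise-linear fit
  init <- best_two_segment(xn, yi)
  prod0 <- (ya - init$m1 * xa - init$c1) * (ya - init$m2 * xa - init$c2)
  k0 <- max(mean(prod0), 1e-4)
  obj <- function(p) {
    r <- (ya - p[1] * xa - p[2]) * (ya - p[3] * xa - p[4]) - exp(p[5])
    sum(r^2)
  }
  grad <- function(p) {
    a <- ya - p[1] * xa - p[2]
    b <- ya - p[3] * xa - p[4]
    k <- exp(p[5])
    r <- a * b - k
    2 * c(sum(r * (-xa * b)), sum(r * (-b)),
          sum(r * (-xa * a)), sum(r * (-a)), sum(r * (-k)))
  }
  fit <- tryCatch(
    optim(c(init$m1, init$c1, init$m2, init$c2, log(k0)), obj, gr = grad,
          method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed("optim_failure"))
  p <- fit$par
  m1 <- p[1]; c1 <- p[2]; m2 <- p[3]; c2 <- p[4]; k <- exp(p[5])
  rmse <- sqrt(fit$value / length(xa))
  if (abs(m1 - m2) < min_slope_sep || rmse > max_rmse) {
    res <- failed(if (abs(m1 - m2) < min_slope_sep) "degenerate_slopes"
                  else "poor_fit")
    res$asymptote1 <- c(slope = m1, intercept = c1)
    res$asymptote2 <- c(slope = m2, intercept = c2)
    res$k <- k; res$rmse <- rmse
    return(res)
  }
  xc <- (c2 - c1) / (m1 - m2)
  yc <- m1 * xc + c1

  # hyperbola point sharing each data abscissa, branch nearest the data
  l1 <- m1 * xa + c1
  l2 <- m2 * xa + c2
  disc <- sqrt((l1 - l2)^2 + 4 * k)
  y_hi <- (l1 + l2 + disc) / 2
  y_lo <- (l1 + l2 - disc) / 2
  yh <- ifelse(abs(y_hi - ya) < abs(y_lo - ya), y_hi, y_lo)
  d2 <- (xa - xc)^2 + (yh - yc)^2
  x_star <- xa[which.min(d2)]

  # back to frames
  t_star <- x_star * diff(range(t_rel[ok])) + min(t_rel[ok])
  # local two-line refinement: the power-law growth segment is concave, so
  # the fitted asymptote is a chord and the hyperbola center lands a few
  # frames late; intersecting lines fit locally around the estimate (where
  # the power law is nearly linear) removes that bias
  t_star <- refine_corner(t_rel, v, t_star)
  # snap to the nearest valid record within two frames
  frame_star <- f0 + round(t_star)
  cand <- fr[ok]
  cand <- cand[abs(cand - frame_star) <= 2]
  if (!length(cand)) return(failed("no_valid_frame_near_transition"))
  tf <- cand[which.min(abs(cand - frame_star))]
  structure(list(asymptote1 = c(slope = m1, intercept = c1),
                 asymptote2 = c(slope = m2, intercept = c2),
                 k = k, center = c(x = xc, y = yc),
                 transition_frame = as.integer(tf), rmse = rmse,
                 valid = TRUE, low_confidence = low_conf, reason = "ok"),
            class = "ng_transition_fit")
}

# iterate: fit a line to the frames at or before the current corner
# estimate and another to a short window just after it, and move the
# estimate to their intersection
refine_corner <- function(t_rel, v, t0, n_iter = 3L, post_window = 12) {
  for (it in seq_len(n_iter)) {
    pre <- which(t_rel <= t0 & !is.na(v))
    post <- which(t_rel > t0 & t_rel <= t0 + post_window & !is.na(v))
    if (length(pre) < 3 || length(post) < 3) return(t0)
    f1 <- lm.fit(cbind(1, t_rel[pre]), v[pre])$coefficients
    f2 <- lm.fit(cbind(1, t_rel[post]), v[post])$coefficients
    if (abs(f1[2] - f2[2]) < 1e-9) return(t0)
    xc <- (f2[1] - f1[1]) / (f1[2] - f2[2])
    t0 <- min(max(xc, min(t_rel) + 1), max(t_rel) - 1)
  }
  t0
}

# exhaustive two-segment piecewise-linear least squares; returns the two
# segment lines at the best breakpoint
best_two_segment <- function(x, y) {
  n <- length(x)
  best <- list(sse = Inf)
  for (b in 3:(n - 2)) {
    i1 <- 1:b; i2 <- b:n
    f1 <- lm.fit(cbind(1, x[i1]), y[i1])
    f2 <- lm.fit(cbind(1, x[i2]), y[i2])
    sse <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (sse < best$sse) {
      best <- list(sse = sse, b = b,
                   m1 = f1$coefficients[2], c1 = f1$coefficients[1],
                   m2 = f2$coefficients[2], c2 = f2$coefficients[1])
    }
  }
  best
}

#' Detect transitions for every trajectory
#'
#' @param trajs Named list of trajectories.
#' @param ... Passed to [detect_transition()].
#' @return The trajectories with `transition_frame` and `transition_fit`
#'   set (NA frame when detection failed; such tracks are later dropped by
#'   [select_full_interphase()]).
#' @export
detect_transitions <- function(trajs, ...) {
  lapply(trajs, function(t) {
    fit <- detect_transition(t, ...)
    t$transition_frame <- fit$transition_frame
    t$transition_fit <- fit
    t
  })
}

#' Normalized interphase time
#'
#' Min-max normalization of time over the interphase: 0 at lamin-shell
#' formation, 1 at breakdown.
#'
#' @param traj A trajectory with formation and breakdown frames.
#' @return Numeric vector aligned with the trajectory's records.
#' @export
normalized_interphase_time <- function(traj) {
  if (is.na(traj$formation_frame) || is.na(traj$breakdown_frame))
    stop("formation and breakdown frames required")
  if (traj$breakdown_frame <= traj$formation_frame)
    stop("breakdown must follow formation")
  (traj$data$frame - traj$formation_frame) /
    (traj$breakdown_frame - traj$formation_frame)
}

#' Fit a power law to the growth phase
#'
#' Nonlinear least squares of \eqn{V(t) = V_{start} + r t^\alpha} on raw
#' volumes, with `t` in hours since the transition. The fit profiles out
#' the linear parameters: for fixed \eqn{\alpha}, \eqn{(V_{start}, r)} solve
#' an ordinary regression on \eqn{t^\alpha}, and \eqn{\alpha} is optimised
#' on `alpha_bounds`.
#'
#' @param traj A trajectory with valid transition and breakdown frames.
#' @param frame_interval_min Minutes per frame.
#' @param alpha_bounds Exponent bounds (default `c(0.2, 3)`).
#' @param min_points Minimum usable frames between transition and breakdown
#'   (default 20).
#' @return A list of class `ng_power_law_fit`: `v_start_fit`, `r`, `alpha`,
#'   `rmse`, `valid`, `reason`.
#' @export
fit_power_law <- function(traj, frame_interval_min = 5,
                          alpha_bounds = c(0.2, 3), min_points = 20L) {
  failed <- function(reason) {
    structure(list(v_start_fit = NA_real_, r = NA_real_, alpha = NA_real_,
                   rmse = NA_real_, valid = FALSE, reason = reason),
              class = "ng_power_law_fit")
  }
  if (is.na(traj$transition_frame) || is.na(traj$breakdown_frame))
    return(failed("missing_endpoints"))
  d <- traj$data
  sel <- d$frame >= traj$transition_frame & d$frame <= traj$breakdown_frame
  v <- clean_volume(traj)[sel]
  t_h <- (d$frame[sel] - traj$transition_frame) * frame_interval_min / 60
  ok <- !is.na(v)
  if (sum(ok) < min_points) return(failed("too_few_points"))
  v <- v[ok]; t_h <- t_h[ok]
  if (sd(v) < 1e-12) return(failed("flat_volume"))

  sse_alpha <- function(alpha) {
    f <- lm.fit(cbind(1, t_h^alpha), v)
    sum(f$residuals^2)
  }
  alpha <- if (diff(alpha_bounds) < 1e-12) alpha_bounds[1]
           else optimize(sse_alpha, interval = alpha_bounds, tol = 1e-9)$minimum
  fin <- lm.fit(cbind(1, t_h^alpha), v)
  v0 <- fin$coefficients[1]; r <- fin$coefficients[2]
  rmse <- sqrt(sum(fin$residuals^2) / length(v))
  # alpha is unidentifiable when the fitted rate is (numerically) zero
  if (abs(r) < 1e-6 * max(abs(v))) return(failed("rate_near_zero"))
  structure(list(v_start_fit = unname(v0), r = unname(r), alpha = alpha,
                 rmse = rmse, valid = TRUE, reason = "ok"),
            class = "ng_power_law_fit")
}

#' Transient growth rate series
#'
#' Centered finite difference
#' \deqn{\Delta V/\Delta T = (V(t + \Delta T/2) - V(t - \Delta T/2))/\Delta T}
#' with a default 4-hour window. The rate is missing wherever either window
#' endpoint lacks a value, the window extends outside the track, or `t` is
#' not more than two hours after formation and at least 30 minutes before
#' breakdown.
#'
#' @param traj A trajectory with formation and breakdown frames.
#' @param window_h Window \eqn{\Delta T} in hours (default 4).
#' @param frame_interval_min Minutes per frame.
#' @param trim_after_formation_h,trim_before_breakdown_min Validity trim
#'   around the lifecycle events (defaults 2 h and 30 min).
#' @return A list of class `ng_rate_series`: `frame`, `time_min`,
#'   `rate` (um^3/h, NA where invalid), `valid`.
#' @export
transient_growth_rate <- function(traj, window_h = 4,
                                  frame_interval_min = 5,
                                  trim_after_formation_h = 2,
                                  trim_before_breakdown_min = 30) {
  stopifnot(window_h > 0)
  d <- traj$data
  v <- clean_volume(traj)
  n <- nrow(d)
  half <- max(1L, round(window_h * 60 / frame_interval_min / 2))
  dt_h <- 2 * half * frame_interval_min / 60
  rate <- rep(NA_real_, n)
  idx <- seq_len(n)
  lo <- idx - half
  hi <- idx + half
  okw <- lo >= 1 & hi <= n
  rate[okw] <- (v[hi[okw]] - v[lo[okw]]) / dt_h
  t_min <- d$frame * frame_interval_min
  if (!is.na(traj$formation_frame)) {
    t_form <- traj$formation_frame * frame_interval_min
    rate[t_min - t_form <= trim_after_formation_h * 60] <- NA
  }
  if (!is.na(traj$breakdown_frame)) {
    t_bd <- traj$breakdown_frame * frame_interval_min
    rate[t_bd - t_min < trim_before_breakdown_min] <- NA
  }
  structure(list(frame = d$frame, time_min = t_min, rate = rate,
                 valid = !is.na(rate), window_h = dt_h),
            class = "ng_rate_series")
}

#' Early and late mean transient rates
#'
#' Means over the first 30\% and the last 25\% of the valid rate windows
#' (ordered by time), and their difference (late minus early) — a proxy for
#' how super-linear a trajectory is.
#'
#' @param series An `ng_rate_series` from [transient_growth_rate()].
#' @return List with `early_mean`, `late_mean`, `difference` (NA when a
#'   segment is empty).
#' @export
early_late_rates <- function(series) {
  r <- series$rate[series$valid]
  n <- length(r)
  if (n < 1) return(list(early_mean = NA_real_, late_mean = NA_real_,
                         difference = NA_real_))
  n_early <- ceiling(0.30 * n)
  n_late <- ceiling(0.25 * n)
  early <- mean(r[seq_len(n_early)])
  late <- mean(r[(n - n_late + 1):n])
  list(early_mean = early, late_mean = late, difference = late - early)
}

#' Scalar growth summary of one trajectory
#'
#' Starting volume is the volume at the transition (start of growth), ending
#' volume at breakdown (each falling back to the nearest valid record within
#' two frames), added volume their difference, fold-change their ratio,
#' growth duration the transition-to-breakdown span in hours, and growth
#' rate the added volume divided by the duration.
#'
#' @param traj A trajectory with valid transition and breakdown frames.
#' @param frame_interval_min Minutes per frame.
#' @param alpha Optional fitted exponent to carry along (default: fit here).
#' @return One-row `data.table` (`track_id, starting_volume, ending_volume,
#'   added_volume, fold_change, growth_duration_h, growth_rate, alpha`), or
#'   NULL when an endpoint volume is unavailable.
#' @export
growth_summary <- function(traj, frame_interval_min = 5, alpha = NULL) {
  if (is.na(traj$transition_frame) || is.na(traj$breakdown_frame))
    return(NULL)
  vs <- volume_near_frame(traj, traj$transition_frame)
  ve <- volume_near_frame(traj, traj$breakdown_frame)
  if (is.na(vs) || is.na(ve)) return(NULL)
  if (is.null(alpha)) {
    pf <- fit_power_law(traj, frame_interval_min = frame_interval_min)
    alpha <- if (pf$valid) pf$alpha else NA_real_
  }
  dur_h <- (traj$breakdown_frame - traj$transition_frame) *
    frame_interval_min / 60
  data.table::data.table(
    track_id = traj$track_id, starting_volume = vs, ending_volume = ve,
    added_volume = ve - vs, fold_change = ve / vs,
    growth_duration_h = dur_h, growth_rate = (ve - vs) / dur_h,
    alpha = alpha)
}

#' Growth summaries for a set of trajectories
#'
#' @param trajs Named list of trajectories with transitions set.
#' @param frame_interval_min Minutes per frame.
#' @return `data.table` of [growth_summary()] rows (tracks without usable
#'   endpoints are dropped).
#' @export
growth_summaries <- function(trajs, frame_interval_min = 5) {
  rows <- lapply(trajs, growth_summary, frame_interval_min = frame_interval_min)
  data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
}

#' Mode of a distribution by Gaussian kernel density
#'
#' Used for the peak of the fold-change distribution; bandwidth by
#' Silverman's rule of thumb.
#'
#' @param x Numeric values.
#' @return The abscissa of the density maximum.
#' @export
density_mode <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 2)
  dd <- stats::density(x, bw = "nrd0")
  dd$x[which.max(dd$y)]
}
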