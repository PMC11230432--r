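# Population-level adder statistics, colony-time stratification and
# bootstrap confidence intervals. Includes the moment-matched adder
# simulations used to interpret the population correlations: at the adder
# steady state with symmetric division, CV(added)/CV(ending) = sqrt(3).

#' Coefficient of variation
#'
#' Sample (n-1) standard deviation divided by the mean.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return Dimensionless CV.
#' @export
cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("cv needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("cv undefined for zero mean")
  sd(values) / m
}

#' Adder diagnostic panel
#'
#' Pearson correlations of fold-change, added volume, growth rate and
#' growth duration with starting volume (with two-sided p-values), the CVs
#' of added and ending volume, and their ratio. Under adder-like size
#' control the added-volume correlation is ~0 and the CV ratio is ~sqrt(3)
#' at steady state.
#'
#' @param summaries Growth-summary table ([growth_summaries()]).
#' @return A list of class `ng_adder_panel`: `correlations` (data.table
#'   `feature, r, p, n`), `cv_added`, `cv_ending`, `cv_ratio`.
#' @export
adder_panel <- function(summaries) {
  s <- data.table::as.data.table(summaries)
  if (nrow(s) < 10) stop("need at least 10 growth summaries")
  feats <- c(fold_change = "fold_change", added_volume = "added_volume",
             growth_rate = "growth_rate", growth_duration_h = "growth_duration_h")
  rows <- lapply(names(feats), function(f) {
    xx <- s$starting_volume; yy <- s[[feats[[f]]]]
    ok <- !is.na(xx) & !is.na(yy)
    if (sum(ok) < 3 || sd(xx[ok]) == 0 || sd(yy[ok]) == 0)
      return(data.table::data.table(feature = f, r = NA_real_, p = NA_real_,
                                    n = sum(ok)))
    ct <- cor.test(xx[ok], yy[ok])
    data.table::data.table(feature = f, r = unname(ct$estimate),
                           p = ct$p.value, n = sum(ok))
  })
  cva <- if (sd(s$added_volume, na.rm = TRUE) == 0) 0 else cv(s$added_volume)
  cve <- cv(s$ending_volume)
  structure(list(correlations = data.table::rbindlist(rows),
                 cv_added = cva, cv_ending = cve,
                 cv_ratio = cva / cve),
            class = "ng_adder_panel")
}

#' Rolling mean over aligned colony time
#'
#' @param values Feature values.
#' @param colony_times Aligned colony times (hours) matched to `values`.
#' @param window_h Rolling window width in hours.
#' @param centers Evaluation times (default: the sorted observed times).
#' @return `data.table` with `time`, `rolling_mean`, `n` (NA mean where a
#'   window is empty).
#' @export
stratify_by_colony_time <- function(values, colony_times, window_h,
                                    centers = NULL) {
  stopifnot(length(values) == length(colony_times), window_h > 0)
  ok <- !is.na(values) & !is.na(colony_times)
  v <- values[ok]; tt <- colony_times[ok]
  if (is.null(centers)) centers <- sort(unique(tt))
  half <- window_h / 2
  res <- vapply(centers, function(cc) {
    sel <- tt >= cc - half & tt <= cc + half
    c(if (any(sel)) mean(v[sel]) else NA_real_, sum(sel))
  }, numeric(2))
  data.table::data.table(time = centers, rolling_mean = res[1, ],
                         n = as.integer(res[2, ]))
}

#' Bootstrap confidence interval for a Pearson correlation
#'
#' Resamples the paired observations with replacement `n_resamples` times
#' (default 500), computes a Pearson correlation per resample (degenerate
#' zero-variance resamples are dropped), and reports the 5th and 95th
#' percentiles — a 90\% interpercentile confidence band.
#'
#' @param x,y Paired observations (pairs with missing values are dropped).
#' @param n_resamples Number of bootstrap resamples (default 500).
#' @param probs CI percentiles (default `c(0.05, 0.95)`).
#' @return A list of class `ng_boot_ci`: `estimate`, `lower`, `upper`,
#'   `n`, `n_resamples`, `resamples`.
#' @export
bootstrap_corr_ci <- function(x, y, n_resamples = 500, probs = c(0.05, 0.95)) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  rs <- vapply(seq_len(n_resamples), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sd(x[idx]) == 0 || sd(y[idx]) == 0) return(NA_real_)
    cor(x[idx], y[idx])
  }, numeric(1))
  rs <- rs[!is.na(rs)]
  if (!length(rs)) stop("all bootstrap resamples degenerate")
  q <- quantile(rs, probs, names = FALSE)
  structure(list(estimate = cor(x, y), lower = q[1], upper = q[2],
                 n = n, n_resamples = n_resamples, resamples = rs),
            class = "ng_boot_ci")
}

#' Bootstrap confidence interval for an arbitrary statistic
#'
#' @param values Numeric vector.
#' @param stat Function of a numeric vector (e.g. [cv()]).
#' @param n_resamples Number of resamples (default 500).
#' @param probs CI percentiles (default `c(0.05, 0.95)`).
#' @return List with `estimate`, `lower`, `upper`.
#' @export
bootstrap_stat_ci <- function(values, stat = cv, n_resamples = 500,
                              probs = c(0.05, 0.95)) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  rs <- vapply(seq_len(n_resamples), function(b) {
    stat(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  q <- quantile(rs, probs, names = FALSE)
  list(estimate = stat(values), lower = q[1], upper = q[2])
}

#' Steady-state adder lineage simulation
#'
#' Iterates the adder map with symmetric division,
#' \eqn{V_{start,n+1} = (V_{start,n} + \Delta V_n)/2}, with added volumes
#' drawn iid from a truncated normal. After burn-in the starting-volume
#' distribution reaches the adder steady state, where
#' CV(added)/CV(ending) = sqrt(3) and the mean fold-change is 2.
#'
#' @param n_generations Generations recorded after burn-in.
#' @param mean_added Mean added volume (default 517.9 um^3).
#' @param cv_added Added-volume CV (default 0.177).
#' @param burn_in Generations discarded (default 100).
#' @param v0 Initial starting volume (default `mean_added`).
#' @return `data.table` with `v_start`, `added`, `v_end`, `fold_change`.
#' @export
simulate_adder_lineage <- function(n_generations = 10000,
                                   mean_added = 517.9, cv_added = 0.177,
                                   burn_in = 100, v0 = mean_added) {
  n_tot <- n_generations + burn_in
  added <- rnorm_trunc(n_tot, mean_added, cv_added * mean_added, lower = 0)
  v_start <- numeric(n_tot)
  v <- v0
  for (i in seq_len(n_tot)) {
    v_start[i] <- v
    v <- (v + added[i]) / 2
  }
  keep <- (burn_in + 1):n_tot
  data.table::data.table(v_start = v_start[keep], added = added[keep],
                         v_end = v_start[keep] + added[keep],
                         fold_change = (v_start[keep] + added[keep]) /
                           v_start[keep])
}

#' Moment-matched independent-adder population
#'
#' Draws starting volumes and independent added volumes from truncated
#' normals with the study's printed moments (517.9 +/- 54.9 um^3 starting;
#' added mean 517.9 with CV 0.177). With added volume independent of
#' starting volume, the fold-change (V_start + added)/V_start is negatively
#' correlated with starting volume (~ -0.52) while added volume itself is
#' uncorrelated — the adder signature.
#'
#' @param n Population size per replicate (default 1166, the study's
#'   full-interphase track count).
#' @param mean_start,sd_start Starting-volume moments.
#' @param mean_added,cv_added Added-volume moments.
#' @return `data.table` with `v_start`, `added`, `v_end`, `fold_change`.
#' @export
simulate_adder_population <- function(n = 1166, mean_start = 517.9,
                                      sd_start = 54.9, mean_added = 517.9,
                                      cv_added = 0.177) {
  v_start <- rnorm_trunc(n, mean_start, sd_start, lower = 0)
  added <- rnorm_trunc(n, mean_added, cv_added * mean_added, lower = 0)
  data.table::data.table(v_start = v_start, added = added,
                         v_end = v_start + added,
                         fold_change = (v_start + added) / v_start)
}
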