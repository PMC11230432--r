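# Automated trajectory quality control: field-of-view edge exclusion,
# minimum track length, rolling-median volume outlier flagging, and the
# full-interphase trajectory filter.

#' Mark field-of-view-edge records as excluded
#'
#' Records whose segmentation touches the FOV boundary do not capture the
#' whole nucleus; they are retained in the trajectory but marked excluded so
#' downstream feature computations treat them as missing.
#'
#' @param trajs Named list of trajectories.
#' @return The trajectories with an `excluded` column set on each record.
#' @export
flag_fov_edge <- function(trajs) {
  out <- lapply(trajs, function(t) {
    d <- t$data
    prior <- if ("excluded" %in% names(d)) d$excluded else FALSE
    d[, excluded := (prior | fov_edge)]
    d[is.na(excluded), excluded := FALSE]
    t$data <- d
    t
  })
  n_flagged <- sum(vapply(out, function(t) sum(t$data$excluded, na.rm = TRUE),
                          numeric(1)))
  attr(out, "ng_log") <- list(rule = "fov_edge", records_excluded = n_flagged)
  out
}

#' Drop trajectories shorter than a minimum number of frames
#'
#' Tracks shorter than five frames (the default) are usually debris or
#' merged-object segmentation incidents. Length counts observed records
#' (rows with a measured volume), not gap placeholders.
#'
#' @param trajs Named list of trajectories.
#' @param min_track_frames Minimum observed frames (default 5).
#' @return Filtered trajectory list; removal counts in the `ng_log`
#'   attribute.
#' @export
filter_min_length <- function(trajs, min_track_frames = 5L) {
  n_obs <- vapply(trajs, function(t) sum(!is.na(t$data$volume)), numeric(1))
  keep <- n_obs >= min_track_frames
  out <- trajs[keep]
  attr(out, "ng_log") <- list(rule = "min_track_length",
                              tracks_in = length(trajs),
                              tracks_removed = sum(!keep),
                              tracks_retained = sum(keep))
  out
}

# centered rolling median with the study's asymmetric padding: the head is
# padded with the first volume value, the tail with the median of the last
# three volumes (so genuine rapid early growth is not flagged while
# end-of-track mitotic jumps are)
rolling_median_padded <- function(v, window) {
  n <- length(v)
  half <- (window - 1L) %/% 2L
  obs <- v[!is.na(v)]
  if (!length(obs)) return(rep(NA_real_, n))
  head_pad <- rep(obs[1], half)
  tail_pad <- rep(median(tail(obs, 3)), half)
  vp <- c(head_pad, v, tail_pad)
  vapply(seq_len(n), function(i) {
    w <- vp[i:(i + 2L * half)]
    if (all(is.na(w))) NA_real_ else median(w, na.rm = TRUE)
  }, numeric(1))
}

#' Flag rolling-median volume outliers
#'
#' A timepoint is flagged when its volume deviates by more than
#' `outlier_fraction` (default 15\%) from the median volume within a centered
#' rolling window of `outlier_window_frames` frames (default 15, i.e. 75
#' minutes). Flagged frames become missing values downstream.
#'
#' @param traj A trajectory.
#' @param params [qc_params()].
#' @return The trajectory with `is_tp_outlier` set per record.
#' @export
flag_volume_outliers <- function(traj, params = qc_params()) {
  v <- traj$data$volume
  med <- rolling_median_padded(v, params$outlier_window_frames)
  flag <- !is.na(v) & !is.na(med) & med > 0 &
    abs(v - med) / med > params$outlier_fraction
  traj$data[, is_tp_outlier := flag]
  traj
}

#' Apply the outlier flag to every trajectory
#' @param trajs Named list of trajectories.
#' @param params [qc_params()].
#' @return The trajectories, with flag counts in the `ng_log` attribute.
#' @export
flag_volume_outliers_all <- function(trajs, params = qc_params()) {
  out <- lapply(trajs, flag_volume_outliers, params = params)
  attr(out, "ng_log") <- list(
    rule = "tp_outlier",
    records_flagged = sum(vapply(out, function(t)
      sum(t$data$is_tp_outlier, na.rm = TRUE), numeric(1))))
  out
}

# volumes usable for feature computations: excluded and outlier records are
# missing
clean_volume <- function(traj) {
  v <- traj$data$volume
  if ("excluded" %in% names(traj$data)) v[traj$data$excluded %in% TRUE] <- NA
  v[traj$data$is_tp_outlier %in% TRUE] <- NA
  v[traj$data$fov_edge %in% TRUE] <- NA
  v
}

# volume at a frame, falling back to the nearest valid record within +/- tol
volume_near_frame <- function(traj, frame, tol = 2L) {
  v <- clean_volume(traj)
  f <- traj$data$frame
  cand <- which(!is.na(v) & abs(f - frame) <= tol)
  if (!length(cand)) return(NA_real_)
  v[cand[which.min(abs(f[cand] - frame))]]
}

#' Select full-interphase trajectories
#'
#' A trajectory qualifies when it has formation and breakdown events, a
#' successfully calculated transition point, spans at least
#' `min_full_interphase_frames` frames (default 120, i.e. 10 hours), and has
#' a non-negative overall growth rate.
#'
#' @param trajs Named list of trajectories (with `transition_frame` set,
#'   e.g. by [detect_transitions()]).
#' @param params [qc_params()].
#' @return Filtered list; per-rule removal counts in the `ng_log` attribute.
#' @export
select_full_interphase <- function(trajs, params = qc_params()) {
  reasons <- vapply(trajs, function(t) {
    if (is.na(t$formation_frame)) return("no_formation")
    if (is.na(t$breakdown_frame)) return("no_breakdown")
    if (is.na(t$transition_frame)) return("no_transition")
    span <- t$breakdown_frame - t$formation_frame + 1L
    if (span < params$min_full_interphase_frames) return("too_short")
    vs <- volume_near_frame(t, t$transition_frame)
    ve <- volume_near_frame(t, t$breakdown_frame)
    if (is.na(vs) || is.na(ve)) return("missing_endpoint_volume")
    if (ve < vs) return("negative_growth")
    "pass"
  }, character(1))
  out <- trajs[reasons == "pass"]
  attr(out, "ng_log") <- list(rule = "full_interphase",
                              tracks_in = length(trajs),
                              tracks_retained = length(out),
                              removed_by_reason = table(reasons[reasons != "pass"]))
  out
}

#' Flag abnormally long growth durations
#'
#' Optional automated stand-in for the study's manual curation of a small
#' (~3.5\%) long-duration subpopulation: flags trajectories whose growth
#' duration exceeds the population mean + 3 SD. Off by default.
#'
#' @param trajs Full-interphase trajectories with transitions set.
#' @param frame_interval_min Minutes per frame.
#' @return Logical vector named by track id.
#' @export
flag_long_durations <- function(trajs, frame_interval_min = 5) {
  dur <- vapply(trajs, function(t) {
    (t$breakdown_frame - t$transition_frame) * frame_interval_min / 60
  }, numeric(1))
  thr <- mean(dur, na.rm = TRUE) + 3 * sd(dur, na.rm = TRUE)
  !is.na(dur) & dur > thr
}
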