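# Frame-to-frame linking of detected nuclei and gap closing. Linking is a
# minimum-cost assignment between consecutive frames: every detection in
# frame t and frame t+1 is a node, each node also has a virtual partner
# (track end / track birth) at fixed cost, and the transportation problem
# with unit masses reduces to a rectangular linear assignment solved exactly.
# Mitosis is never linked: daughters start new tracks.

#' Construct a per-frame detection set
#'
#' @param frame Integer frame index.
#' @param detection_id Integer ids, unique within the frame.
#' @param x,y,z Centroid coordinates (um).
#' @param volume Volumes (um^3).
#' @param fov_edge Logical: segmentation touches the field-of-view border.
#' @return A `data.table` of class `ng_detections`.
#' @export
frame_detections <- function(frame, detection_id, x, y, z = 0, volume,
                             fov_edge = FALSE) {
  d <- data.table::data.table(
    frame = as.integer(frame), detection_id = as.integer(detection_id),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    volume = as.numeric(volume), fov_edge = as.logical(fov_edge))
  if (anyDuplicated(d$detection_id))
    stop("detection_ids must be unique within a frame")
  if (length(unique(d$frame)) > 1) stop("one frame index per detection set")
  data.table::setorder(d, detection_id)
  structure(d, class = c("ng_detections", class(d)))
}

# link cost: normalized centroid distance plus weighted relative volume
# difference; Inf when beyond the distance gate
link_cost_matrix <- function(a, b, params) {
  na <- nrow(a); nb <- nrow(b)
  dx <- outer(a$x, b$x, `-`); dy <- outer(a$y, b$y, `-`)
  dz <- outer(a$z, b$z, `-`)
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  vmean <- outer(a$volume, b$volume, `+`) / 2
  vfrac <- abs(outer(a$volume, b$volume, `-`)) / vmean
  cost <- dist / params$max_link_distance_um +
    params$volume_cost_weight * vfrac
  cost[dist > params$max_link_distance_um] <- Inf
  cost[vfrac > params$max_volume_frac] <- Inf
  cost
}

# augment an na x nb real-cost matrix with virtual rows/columns and solve;
# returns integer matrix of (row index in a, col index in b) matched pairs
solve_augmented <- function(cost, birth_death_cost) {
  na <- nrow(cost); nb <- ncol(cost)
  n <- na + nb
  BIG <- 1e6
  full <- matrix(BIG, n, n)
  finite_cost <- cost
  finite_cost[!is.finite(finite_cost)] <- BIG
  if (na && nb) full[seq_len(na), seq_len(nb)] <- finite_cost
  for (i in seq_len(na)) full[i, nb + i] <- birth_death_cost
  for (j in seq_len(nb)) full[na + j, j] <- birth_death_cost
  if (na && nb) full[na + seq_len(nb), nb + seq_len(na)] <- 0
  assign <- lap_solve(full)
  pairs <- which(assign[seq_len(na)] <= nb)
  cbind(a = pairs, b = assign[pairs])
}

#' Link detections between two consecutive frames
#'
#' Solves the minimum-cost assignment between the two detection sets, with a
#' virtual node per detection at cost `birth_death_cost` representing track
#' birth or end. Links are only admissible within
#' `max_link_distance_um`; each detection is linked to at most one partner
#' and the total cost is minimal over all feasible assignments.
#'
#' @param a,b [frame_detections()] for frames `t` and `t+1`.
#' @param params [link_params()].
#' @return `data.table` with columns `id_a`, `id_b`, `cost` (possibly empty).
#' @export
link_frames <- function(a, b, params = link_params()) {
  if (nrow(a) && nrow(b) && b$frame[1] != a$frame[1] + 1L)
    stop("frames must be consecutive")
  empty <- data.table::data.table(id_a = integer(0), id_b = integer(0),
                                  cost = numeric(0))
  if (!nrow(a) || !nrow(b)) return(empty)
  cost <- link_cost_matrix(a, b, params)
  if (!any(is.finite(cost))) return(empty)
  m <- solve_augmented(cost, params$birth_death_cost)
  if (!nrow(m)) return(empty)
  keep <- is.finite(cost[m])
  m <- m[keep, , drop = FALSE]
  data.table::data.table(id_a = a$detection_id[m[, "a"]],
                         id_b = b$detection_id[m[, "b"]],
                         cost = cost[m])
}

#' Build tracks from a sequence of frame detections
#'
#' Runs [link_frames()] over each consecutive frame pair and chains maximal
#' link sequences into tracks with fresh track ids (assigned in order of
#' first appearance).
#'
#' @param frames List of [frame_detections()], sorted by frame.
#' @param params [link_params()].
#' @return A `data.table` (track table) with columns `track_id, frame,
#'   detection_id, x, y, z, volume, fov_edge`, one row per detection.
#' @export
build_tracks <- function(frames, params = link_params()) {
  fidx <- vapply(frames, function(f) if (nrow(f)) f$frame[1] else NA_integer_,
                 integer(1))
  known <- fidx[!is.na(fidx)]
  if (is.unsorted(known, strictly = TRUE)) stop("frames must be sorted")
  rows <- list()
  next_id <- 1L
  prev_track <- NULL # map detection_id -> track_id in previous frame
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!nrow(f)) { prev_track <- NULL; next }
    cur_track <- rep(NA_integer_, nrow(f))
    consecutive <- k > 1 && nrow(frames[[k - 1]]) &&
      frames[[k - 1]]$frame[1] + 1L == f$frame[1]
    if (consecutive && !is.null(prev_track)) {
      links <- link_frames(frames[[k - 1]], f, params)
      if (nrow(links)) {
        ia <- match(links$id_a, frames[[k - 1]]$detection_id)
        ib <- match(links$id_b, f$detection_id)
        cur_track[ib] <- prev_track[ia]
      }
    }
    fresh <- which(is.na(cur_track))
    if (length(fresh)) {
      cur_track[fresh] <- next_id + seq_along(fresh) - 1L
      next_id <- next_id + length(fresh)
    }
    rows[[length(rows) + 1L]] <- data.table::data.table(
      track_id = cur_track, frame = f$frame, detection_id = f$detection_id,
      x = f$x, y = f$y, z = f$z, volume = f$volume, fov_edge = f$fov_edge)
    prev_track <- cur_track
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out)) data.table::setorder(out, track_id, frame)
  out[]
}

#' Close short gaps between track ends and track starts
#'
#' Second tracking round: track ends (no link to the next frame) are matched
#' to track starts beginning up to `gap_max_frames` frames later, by the same
#' cost optimisation. Detections at the field-of-view edge are excluded (a
#' track ending there has likely left the imaged region). Skipped frames
#' remain in the merged track as missing-value records when trajectories are
#' built.
#'
#' @param tracks Track table from [build_tracks()].
#' @param params [link_params()].
#' @return Track table with merged track ids.
#' @export
close_gaps <- function(tracks, params = link_params()) {
  if (!nrow(tracks)) return(tracks)
  tracks <- data.table::copy(tracks)
  repeat {
    ends <- tracks[, .SD[which.max(frame)], by = track_id]
    starts <- tracks[, .SD[which.min(frame)], by = track_id]
    max_frame <- max(tracks$frame)
    min_frame <- min(tracks$frame)
    ends <- ends[frame < max_frame & !fov_edge]
    starts <- starts[frame > min_frame & !fov_edge]
    merged_any <- FALSE
    for (f in sort(unique(ends$frame))) {
      e <- ends[frame == f]
      s <- starts[frame > f & frame <= f + params$gap_max_frames]
      s <- s[!track_id %in% e$track_id]
      if (!nrow(e) || !nrow(s)) next
      cost <- link_cost_matrix(e, s, params)
      if (!any(is.finite(cost))) next
      m <- solve_augmented(cost, params$birth_death_cost)
      if (!nrow(m)) next
      m <- m[is.finite(cost[m]), , drop = FALSE]
      for (r in seq_len(nrow(m))) {
        old <- s$track_id[m[r, "b"]]
        new <- e$track_id[m[r, "a"]]
        tracks[track_id == old, track_id := new]
        merged_any <- TRUE
      }
      if (merged_any) break # recompute ends/starts after merging
    }
    if (!merged_any) break
  }
  data.table::setorder(tracks, track_id, frame)
  tracks[]
}

#' Convert a track table to the feature-table schema
#'
#' Fills feature columns the tracker cannot measure (height, aspect ratio)
#' with missing values and computes `time_min` from the frame interval.
#'
#' @param tracks Track table from [build_tracks()] / [close_gaps()].
#' @param frame_interval_min Minutes per frame.
#' @return A `data.table` in the feature-table schema.
#' @export
tracks_to_feature_table <- function(tracks, frame_interval_min = 5) {
  out <- data.table::copy(tracks)
  out[, time_min := frame * frame_interval_min]
  out[, height := NA_real_]
  out[, aspect_ratio_xy := NA_real_]
  out[, is_tp_outlier := FALSE]
  data.table::setcolorder(out, c("track_id", "frame", "time_min", "x", "y",
                                 "z", "volume", "height", "aspect_ratio_xy",
                                 "fov_edge", "is_tp_outlier"))
  out[]
}
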