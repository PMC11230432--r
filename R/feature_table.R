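# Core domain containers: per-nucleus per-frame feature tables and the
# trajectory objects the pipeline operates on. Tables are plain CSV with a
# fixed documented header; the manifest column names fov_edge and
# is_tp_outlier follow the deposited dataset's naming.

.ng_required_cols <- c("track_id", "frame", "time_min", "x", "y", "z",
                       "volume", "height", "aspect_ratio_xy", "fov_edge",
                       "is_tp_outlier")
.ng_lifecycle_cols <- c("formation_frame", "breakdown_frame")

#' Construct a single-nucleus trajectory
#'
#' A trajectory is the time-ordered set of records of one track, with
#' lifecycle marks (lamin-shell formation and breakdown frames, supplied
#' externally or by the simulator), an optional detected transition frame,
#' and lineage links. Gaps between observed frames are represented as
#' missing-value records so frame indexing stays uniform.
#'
#' @param track_id Integer track label.
#' @param data A data.frame with at least the columns
#'   `frame, time_min, x, y, z, volume, height, aspect_ratio_xy, fov_edge,
#'   is_tp_outlier`; one row per frame, sorted by frame.
#' @param formation_frame,breakdown_frame Optional integer lifecycle frames.
#' @param transition_frame Optional detected start-of-growth frame.
#' @param parent_id,family_id Optional lineage links.
#' @return An object of class `ng_trajectory`.
#' @export
trajectory <- function(track_id, data, formation_frame = NA_integer_,
                       breakdown_frame = NA_integer_,
                       transition_frame = NA_integer_,
                       parent_id = NA_integer_, family_id = NA_integer_) {
  data <- data.table::as.data.table(data)
  miss <- setdiff(setdiff(.ng_required_cols, "track_id"), names(data))
  if (length(miss)) stop("trajectory data missing column(s): ",
                         paste(miss, collapse = ", "))
  data.table::setorder(data, frame)
  if (anyDuplicated(data$frame)) {
    stop("duplicate (track_id, frame): track ", track_id, " frame ",
         data$frame[duplicated(data$frame)][1])
  }
  # fill interior gaps with missing-value records
  if (nrow(data) > 1) {
    full <- seq(min(data$frame), max(data$frame))
    if (length(full) > nrow(data)) {
      skel <- data.table::data.table(frame = full)
      data <- data[skel, on = "frame"]
    }
  }
  if (!is.na(formation_frame) && !is.na(breakdown_frame) &&
      breakdown_frame < formation_frame) {
    stop("breakdown_frame precedes formation_frame for track ", track_id)
  }
  structure(list(track_id = as.integer(track_id), data = data,
                 formation_frame = as.integer(formation_frame),
                 breakdown_frame = as.integer(breakdown_frame),
                 transition_frame = as.integer(transition_frame),
                 parent_id = as.integer(parent_id),
                 family_id = as.integer(family_id)),
            class = "ng_trajectory")
}

#' @export
print.ng_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ng_trajectory %d: %d frames [%s..%s], formation=%s transition=%s breakdown=%s>\n",
    x$track_id, nrow(x$data),
    if (nrow(x$data)) min(x$data$frame) else NA,
    if (nrow(x$data)) max(x$data$frame) else NA,
    x$formation_frame, x$transition_frame, x$breakdown_frame))
  invisible(x)
}

#' Number of frames spanned by a trajectory
#' @param traj An `ng_trajectory`.
#' @return Integer frame count (including gap records).
#' @export
n_frames <- function(traj) nrow(traj$data)

#' Split a feature table into trajectories
#'
#' @param tab A data.frame in the feature-table schema.
#' @param lineage Optional lineage table (`track_id, parent_id, family_id`).
#' @return Named list of [trajectory()] objects keyed by track id.
#' @export
trajectories_from_table <- function(tab, lineage = NULL) {
  tab <- data.table::as.data.table(tab)
  miss <- setdiff(.ng_required_cols, names(tab))
  if (length(miss)) stop("feature table missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab[, list(track_id, frame)])) {
    d <- tab[duplicated(tab[, list(track_id, frame)])][1]
    stop("duplicate (track_id, frame): track ", d$track_id, " frame ", d$frame)
  }
  data.table::setorder(tab, track_id, frame)
  has_life <- all(.ng_lifecycle_cols %in% names(tab))
  lin <- NULL
  if (!is.null(lineage)) {
    lin <- data.table::as.data.table(lineage)
    data.table::setkey(lin, track_id)
  }
  split_tabs <- split(tab, by = "track_id", keep.by = TRUE)
  out <- lapply(split_tabs, function(g) {
    tid <- g$track_id[1]
    ff <- if (has_life) g$formation_frame[1] else NA_integer_
    bf <- if (has_life) g$breakdown_frame[1] else NA_integer_
    pid <- NA_integer_; fid <- NA_integer_
    if (!is.null(lin) && nrow(lin[.(as.integer(tid))]) &&
        !is.na(lin[.(as.integer(tid))]$track_id[1])) {
      row <- lin[.(as.integer(tid))][1]
      pid <- row$parent_id; fid <- row$family_id
    }
    g2 <- g[, setdiff(names(g), c("track_id", .ng_lifecycle_cols)), with = FALSE]
    trajectory(tid, g2, formation_frame = ff, breakdown_frame = bf,
               parent_id = pid, family_id = fid)
  })
  names(out) <- vapply(out, function(t) as.character(t$track_id), character(1))
  out
}

#' Flatten trajectories back into one feature table
#'
#' Inverse of [trajectories_from_table()]: gap records (all-missing rows) are
#' kept so the round trip is lossless.
#'
#' @param trajs Named list of trajectories.
#' @return A `data.table` in the feature-table schema with lifecycle columns.
#' @export
table_from_trajectories <- function(trajs) {
  if (!length(trajs)) {
    empty <- data.table::as.data.table(
      setNames(rep(list(numeric(0)), length(.ng_required_cols)), .ng_required_cols))
    empty[, track_id := integer(0)][, frame := integer(0)]
    empty[, formation_frame := integer(0)][, breakdown_frame := integer(0)]
    return(empty[])
  }
  parts <- lapply(trajs, function(t) {
    d <- data.table::copy(t$data)
    d[, track_id := t$track_id]
    d[, formation_frame := t$formation_frame]
    d[, breakdown_frame := t$breakdown_frame]
    d
  })
  out <- data.table::rbindlist(parts, use.names = TRUE, fill = TRUE)
  data.table::setcolorder(out, c("track_id", setdiff(.ng_required_cols, "track_id"),
                                 .ng_lifecycle_cols))
  data.table::setorder(out, track_id, frame)
  out[]
}

#' Read a feature table from CSV
#'
#' @param path CSV path with the feature-table header. Unknown columns are
#'   preserved and travel with each trajectory's records.
#' @param lineage Optional lineage table joined onto the trajectories.
#' @return Named list of trajectories (see [trajectories_from_table()]).
#' @export
read_feature_table <- function(path, lineage = NULL) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  tab <- data.table::fread(path)
  miss <- setdiff(.ng_required_cols, names(tab))
  if (length(miss)) stop("feature table missing required column(s): ",
                         paste(miss, collapse = ", "))
  for (cc in c("fov_edge", "is_tp_outlier")) tab[[cc]] <- as.logical(tab[[cc]])
  trajectories_from_table(tab, lineage = lineage)
}

#' Write trajectories to a feature-table CSV
#'
#' Lossless inverse of [read_feature_table()] for the documented schema.
#'
#' @param trajs Named list of trajectories (or a data.frame already in table
#'   form).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(trajs, path) {
  tab <- if (is.data.frame(trajs)) data.table::as.data.table(trajs)
         else table_from_trajectories(trajs)
  ok <- tryCatch({ data.table::fwrite(tab, path); TRUE },
                 error = function(e) stop("cannot write feature table to ",
                                          path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a lineage table (`track_id, parent_id, family_id`) from CSV
#'
#' @param path CSV path.
#' @return A `data.table`; validates that no parent has more than two
#'   children and that the parent graph is acyclic.
#' @export
read_lineage_table <- function(path) {
  if (!file.exists(path)) stop("lineage table not found: ", path)
  lin <- data.table::fread(path)
  miss <- setdiff(c("track_id", "parent_id", "family_id"), names(lin))
  if (length(miss)) stop("lineage table missing required column(s): ",
                         paste(miss, collapse = ", "))
  validate_lineage(lin)
  lin
}

#' Write a lineage table to CSV
#' @param lineage Lineage data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(lineage, path) {
  data.table::fwrite(data.table::as.data.table(lineage), path)
  invisible(path)
}

#' Validate lineage-table invariants
#'
#' Checks that each parent has at most two children and that following
#' `parent_id` links never cycles.
#'
#' @param lineage Lineage data.frame.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_lineage <- function(lineage) {
  lin <- data.table::as.data.table(lineage)
  kids <- lin[!is.na(parent_id), .N, by = parent_id]
  if (nrow(kids) && any(kids$N > 2)) {
    stop("lineage integrity: parent ", kids[N > 2]$parent_id[1],
         " has more than two children")
  }
  parent_of <- setNames(lin$parent_id, as.character(lin$track_id))
  for (tid in lin$track_id) {
    seen <- character(0)
    cur <- as.character(tid)
    repeat {
      if (!cur %in% names(parent_of)) break
      p <- parent_of[[cur]]
      if (is.na(p)) break
      if (cur %in% seen) stop("lineage integrity: cycle involving track ", cur)
      seen <- c(seen, cur)
      cur <- as.character(p)
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
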