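# Pipeline orchestration: chains tracking, quality control, growth
# features, colony context and lineage analysis over feature/lineage
# tables, writing per-stage outputs and a summary report with per-filter
# before/after counts.

stage_log <- function(logs, stage, ...) {
  entry <- list(...)
  if (length(entry) == 1 && is.null(names(entry)) && is.list(entry[[1]]))
    entry <- entry[[1]]
  logs[[stage]] <- c(logs[[stage]] %||% list(), list(entry))
  logs
}

#' Run the full analysis pipeline
#'
#' Stages, in order: `track` (re-link detections and close gaps; skipped
#' when `retrack = FALSE`), `qc` (FOV-edge exclusion, minimum length,
#' rolling-median outliers), `features` (transition detection,
#' full-interphase selection, power-law fits, growth summaries), `context`
#' (per-frame Voronoi adjacency, density, normalized colony depth, radial
#' height slope, neighbourhood-averaged rates), `lineage` (related and
#' control pairs, inheritance panel). Every filter's before/after counts
#' are logged; any stage failure aborts with the stage name and cause.
#'
#' @param features Feature table (data.frame) or path to a feature CSV.
#' @param lineage Optional lineage table or CSV path.
#' @param config [pipeline_config()].
#' @param out_dir Output directory for per-stage tables and the JSON
#'   summary report (created if needed); `NULL` skips writing.
#' @param retrack Re-run tracking on the detections extracted from the
#'   input table (default TRUE). Rebuilt tracks are relabelled by majority
#'   overlap with the input track ids so lineage annotations stay attached.
#' @return List with `trajectories`, `summaries`, `context`,
#'   `lineage_results`, `logs`, `report`.
#' @export
run_pipeline <- function(features, lineage = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         retrack = TRUE) {
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  logs <- list()
  feat <- run_stage("input", {
    if (is.character(features)) {
      ft <- data.table::fread(features)
    } else ft <- data.table::as.data.table(features)
    miss <- setdiff(.ng_required_cols, names(ft))
    if (length(miss)) stop("missing required column(s): ",
                           paste(miss, collapse = ", "))
    ft
  })
  lin <- if (is.character(lineage)) read_lineage_table(lineage)
         else if (!is.null(lineage)) data.table::as.data.table(lineage)
         else NULL

  # ---- track ----
  if (retrack) {
    feat <- run_stage("track", {
      relabelled <- retrack_feature_table(feat, config)
      logs <- stage_log(logs, "track",
                         rule = "retrack",
                         detections = sum(!is.na(feat$volume)),
                         tracks_in = length(unique(feat$track_id)),
                         tracks_out = length(unique(relabelled$track_id)))
      relabelled
    })
  }

  # ---- qc ----
  trajs <- run_stage("qc", {
    tr <- trajectories_from_table(feat, lineage = lin)
    tr <- flag_fov_edge(tr)
    logs <- stage_log(logs, "qc", attr(tr, "ng_log"))
    tr2 <- filter_min_length(tr, config$qc$min_track_frames)
    logs <- stage_log(logs, "qc", attr(tr2, "ng_log"))
    if (!length(tr2)) warning("qc: no trajectories retained")
    tr3 <- flag_volume_outliers_all(tr2, config$qc)
    logs <- stage_log(logs, "qc", attr(tr3, "ng_log"))
    tr3
  })

  # ---- features ----
  fres <- run_stage("features", {
    trf <- detect_transitions(trajs,
                              window_frames = config$transition_window_frames)
    full <- select_full_interphase(trf, config$qc)
    logs <- stage_log(logs, "features", attr(full, "ng_log"))
    summ <- growth_summaries(full, config$frame_interval_min)
    if (!nrow(summ)) warning("features: no full-interphase summaries")
    list(trajs = trf, full = full, summaries = summ)
  })

  # ---- context ----
  ctx <- run_stage("context", {
    compute_colony_context(fres$full, config)
  })

  # ---- lineage ----
  lres <- run_stage("lineage", {
    if (is.null(lin) || !nrow(fres$summaries)) {
      NULL
    } else {
      pairs <- find_pairs(lin, fres$summaries)
      meta <- control_metadata(fres$full, fres$summaries,
                               config$frame_interval_min)
      cs <- match_control_sisters(meta)
      cmd <- match_control_mother_daughter(meta)
      logs <- stage_log(logs, "lineage",
                         rule = "pairs",
                         sisters = nrow(pairs$sisters),
                         mother_daughter = nrow(pairs$mother_daughter),
                         control_sisters = nrow(cs),
                         control_mother_daughter = nrow(cmd))
      panel <- NULL
      if (nrow(pairs$sisters) >= 10 && nrow(cs) >= 10) {
        panel <- inheritance_panel(
          pairs$sisters[, list(id1, id2)], cs[, list(id1, id2)],
          fres$summaries, n_boot = config$n_boot)
      }
      list(pairs = pairs, control_sisters = cs,
           control_mother_daughter = cmd, panel = panel)
    }
  })

  report <- list(
    n_input_tracks = length(unique(feat$track_id)),
    n_qc_tracks = length(trajs),
    n_full_interphase = length(fres$full),
    n_summaries = nrow(fres$summaries),
    mean_fold_change = if (nrow(fres$summaries))
      mean(fres$summaries$fold_change) else NA,
    logs = logs)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(table_from_trajectories(fres$full),
                        file.path(out_dir, "full_interphase_features.csv"))
    data.table::fwrite(fres$summaries,
                       file.path(out_dir, "growth_summaries.csv"))
    if (!is.null(ctx$per_frame))
      data.table::fwrite(ctx$per_frame, file.path(out_dir, "colony_context.csv"))
    if (!is.null(ctx$per_colony_frame))
      data.table::fwrite(ctx$per_colony_frame,
                         file.path(out_dir, "colony_summaries.csv"))
    if (!is.null(lres) && !is.null(lres$panel))
      data.table::fwrite(lres$panel, file.path(out_dir, "inheritance_panel.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(trajectories = fres$trajs, full_interphase = fres$full,
       summaries = fres$summaries, context = ctx, lineage_results = lres,
       logs = logs, report = report)
}

# rebuild tracks from the rows of a feature table and relabel rebuilt
# tracks by majority overlap with the input track ids so annotations
# (lifecycle, lineage) stay attached
retrack_feature_table <- function(feat, config) {
  feat <- data.table::as.data.table(feat)
  obs <- feat[!is.na(volume)]
  obs[, detection_id := seq_len(.N)]
  frames <- lapply(sort(unique(obs$frame)), function(f) {
    g <- obs[frame == f]
    frame_detections(f, g$detection_id, g$x, g$y, g$z, g$volume, g$fov_edge)
  })
  tracks <- build_tracks(frames, config$link)
  tracks <- close_gaps(tracks, config$link)
  map <- merge(tracks[, list(detection_id, new_id = track_id)],
               obs[, list(detection_id, track_id)], by = "detection_id")
  # majority vote per rebuilt track
  votes <- map[, .N, by = list(new_id, track_id)]
  data.table::setorder(votes, new_id, -N, track_id)
  winner <- votes[, .SD[1], by = new_id]
  # keep labels unique if two rebuilt tracks claim the same original id
  data.table::setorder(winner, track_id, -N)
  dup <- duplicated(winner$track_id)
  if (any(dup))
    winner$track_id[dup] <- max(obs$track_id) + seq_len(sum(dup))
  relabel <- setNames(winner$track_id, as.character(winner$new_id))
  new_ids <- map$new_id[match(obs$detection_id, map$detection_id)]
  obs[, track_id := relabel[as.character(new_ids)]]
  obs[, detection_id := NULL]
  obs[]
}

#' Per-frame colony-context metrics for a set of trajectories
#'
#' Builds the Voronoi adjacency of each frame's non-excluded nuclei and
#' derives per-nucleus density, neighbour count, normalized distance from
#' colony center and neighbourhood-averaged transient rate, plus per-frame
#' colony summaries (mean height, radial height slope and its Pearson r,
#' mean density).
#'
#' @param trajs Named list of trajectories.
#' @param config [pipeline_config()].
#' @return List with `per_frame` (per-nucleus rows) and `per_colony_frame`.
#' @export
compute_colony_context <- function(trajs, config = pipeline_config()) {
  if (!length(trajs)) return(list(per_frame = NULL, per_colony_frame = NULL))
  tab <- table_from_trajectories(trajs)
  rates <- lapply(trajs, function(t) {
    rs <- transient_growth_rate(t, config$rate_window_h,
                                config$frame_interval_min)
    data.table::data.table(track_id = t$track_id, frame = rs$frame,
                           rate = rs$rate)
  })
  rates <- data.table::rbindlist(rates)
  tab <- merge(tab, rates, by = c("track_id", "frame"), all.x = TRUE)
  per_frame <- list()
  per_colony <- list()
  for (f in sort(unique(tab$frame))) {
    g <- tab[frame == f & !is.na(x) & !(fov_edge %in% TRUE)]
    if (nrow(g) < 3) next
    graph <- tryCatch(voronoi_adjacency(g$x, g$y, ids = g$track_id),
                      error = function(e) NULL)
    if (is.null(graph)) next
    dep <- colony_depth(graph)
    nbr_rate <- neighborhood_mean_rate(g$x, g$y, g$rate,
                                       config$neighborhood_radius_um)
    per_frame[[length(per_frame) + 1L]] <- data.table::data.table(
      track_id = g$track_id, frame = f,
      density = graph$density,
      n_neighbors = lengths(graph$neighbors),
      normalized_depth = dep$normalized_depth,
      depth = dep$depth,
      neighborhood_mean_rate = nbr_rate)
    rs <- tryCatch(radial_height_slope(g$height, dep$normalized_depth),
                   error = function(e) list(slope = NA_real_,
                                            pearson_r = NA_real_))
    per_colony[[length(per_colony) + 1L]] <- data.table::data.table(
      frame = f, n_nuclei = nrow(g),
      mean_height = mean(g$height, na.rm = TRUE),
      radial_slope = rs$slope, radial_r = rs$pearson_r,
      mean_density = mean(graph$density, na.rm = TRUE))
  }
  list(per_frame = data.table::rbindlist(per_frame),
       per_colony_frame = data.table::rbindlist(per_colony))
}
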