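#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis pipeline with the study's
#' stated defaults: 5-minute frame interval, tracking gates, quality-control
#' thresholds, growth-feature window sizes, the 90 um neighbourhood radius and
#' bootstrap settings.
#'
#' @param frame_interval_min Minutes between consecutive frames (default 5).
#' @param link Tracking parameters, see [link_params()].
#' @param qc Quality-control parameters, see [qc_params()].
#' @param transition_window_frames Frames after formation analysed for the
#'   expansion-to-growth transition (default 40).
#' @param rate_window_h Transient growth-rate window \eqn{\Delta T} in hours
#'   (default 4).
#' @param neighborhood_radius_um Radius for neighbourhood-averaged transient
#'   rates (default 90).
#' @param alpha_bounds Lower/upper bounds for the power-law exponent fit
#'   (default `c(0.2, 3)`).
#' @param n_boot Bootstrap resamples for correlation confidence intervals
#'   (default 500).
#' @param boot_probs Bootstrap CI percentiles (default 5th and 95th: a 90\%
#'   interpercentile band).
#' @param min_align_overlap_frames Minimum overlap when lag-aligning colony
#'   mean-height series (default 60).
#' @param seed Integer seed driving all randomised steps.
#' @return An object of class `ng_config` (a validated list).
#' @export
pipeline_config <- function(frame_interval_min = 5,
                            link = link_params(),
                            qc = qc_params(),
                            transition_window_frames = 40,
                            rate_window_h = 4,
                            neighborhood_radius_um = 90,
                            alpha_bounds = c(0.2, 3),
                            n_boot = 500,
                            boot_probs = c(0.05, 0.95),
                            min_align_overlap_frames = 60,
                            seed = 1L) {
  cfg <- list(
    frame_interval_min = frame_interval_min,
    link = link,
    qc = qc,
    transition_window_frames = as.integer(transition_window_frames),
    rate_window_h = rate_window_h,
    neighborhood_radius_um = neighborhood_radius_um,
    alpha_bounds = alpha_bounds,
    n_boot = as.integer(n_boot),
    boot_probs = boot_probs,
    min_align_overlap_frames = as.integer(min_align_overlap_frames),
    seed = as.integer(seed)
  )
  stopifnot(
    frame_interval_min > 0, transition_window_frames > 0, rate_window_h > 0,
    neighborhood_radius_um > 0, length(alpha_bounds) == 2,
    alpha_bounds[1] > 0, alpha_bounds[2] > alpha_bounds[1],
    n_boot > 0, length(boot_probs) == 2, all(boot_probs > 0 & boot_probs < 1),
    min_align_overlap_frames > 0
  )
  structure(cfg, class = "ng_config")
}

#' Tracking (linking) parameters
#'
#' @param max_link_distance_um Maximum centroid displacement allowed for a
#'   frame-to-frame link (default 15 um per 5-minute step).
#' @param volume_cost_weight Weight \eqn{\lambda} of the relative volume
#'   difference in the link cost (default 1).
#' @param birth_death_cost Cost of matching a detection to a virtual node,
#'   i.e. starting or ending a track (default 1.05, just above the worst
#'   admissible real link).
#' @param gap_max_frames Maximum number of frames a gap-closing link may span
#'   (default 3).
#' @param max_volume_frac Maximum admissible relative volume difference
#'   `|dV| / mean(V)` for a link (default 0.4); prevents links between
#'   nuclei of significantly different volumes, e.g. across mitosis where
#'   the volume roughly halves.
#' @return A list of class `ng_link_params`.
#' @export
link_params <- function(max_link_distance_um = 15,
                        volume_cost_weight = 1,
                        birth_death_cost = 1.05,
                        gap_max_frames = 3L,
                        max_volume_frac = 0.4) {
  stopifnot(max_link_distance_um > 0, volume_cost_weight >= 0,
            birth_death_cost > 0, gap_max_frames >= 1, max_volume_frac > 0)
  structure(list(max_link_distance_um = max_link_distance_um,
                 volume_cost_weight = volume_cost_weight,
                 birth_death_cost = birth_death_cost,
                 gap_max_frames = as.integer(gap_max_frames),
                 max_volume_frac = max_volume_frac),
            class = "ng_link_params")
}

#' Trajectory quality-control parameters
#'
#' Defaults follow the automated filters of the study: tracks shorter than 5
#' frames are dropped, volumes deviating more than 15\% from a 15-frame
#' (75-minute) rolling median are flagged as outlier timepoints, and
#' full-interphase trajectories must span at least 120 frames (10 hours).
#'
#' @param min_track_frames Minimum track length in frames (default 5).
#' @param outlier_window_frames Rolling-median window length, odd (default 15).
#' @param outlier_fraction Relative deviation from the rolling median that
#'   flags a timepoint (default 0.15).
#' @param min_full_interphase_frames Minimum full-interphase length (default 120).
#' @param flag_long_durations If `TRUE`, additionally flag trajectories whose
#'   growth duration exceeds mean + 3 sd of the population (off by default;
#'   the study curated these manually).
#' @return A list of class `ng_qc_params`.
#' @export
qc_params <- function(min_track_frames = 5L,
                      outlier_window_frames = 15L,
                      outlier_fraction = 0.15,
                      min_full_interphase_frames = 120L,
                      flag_long_durations = FALSE) {
  stopifnot(min_track_frames >= 1,
            outlier_window_frames >= 3, outlier_window_frames %% 2 == 1,
            outlier_fraction > 0, outlier_fraction < 1,
            min_full_interphase_frames >= 1)
  structure(list(min_track_frames = as.integer(min_track_frames),
                 outlier_window_frames = as.integer(outlier_window_frames),
                 outlier_fraction = outlier_fraction,
                 min_full_interphase_frames = as.integer(min_full_interphase_frames),
                 flag_long_durations = isTRUE(flag_long_durations)),
            class = "ng_qc_params")
}

#' Read a flat `key: value` configuration file
#'
#' Parses the minimal YAML-style format used by the command-line interface:
#' one `key: value` pair per line, `#` comments, numeric values coerced,
#' `true`/`false` to logical, comma-separated values to vectors. Nested keys
#' use a dotted prefix (`link.max_link_distance_um: 20`).
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- m[2]
    val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    conv <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(conv)) conv
      else if (all(tolower(parts) %in% c("true", "false"))) tolower(parts) == "true"
      else val
    out[[key]] <- parsed
  }
  out
}

#' Build a pipeline configuration from a flat key/value list
#'
#' Dotted keys (`link.*`, `qc.*`, `sim.*`) are routed to the corresponding
#' parameter constructors; everything else goes to [pipeline_config()].
#' Unknown keys raise an error.
#'
#' @param kv Named list, e.g. from [read_config_file()].
#' @return A list with elements `config` (class `ng_config`) and `sim`
#'   (class `ng_sim_config`).
#' @export
config_from_keyvals <- function(kv) {
  if (!length(kv))
    return(list(config = pipeline_config(), sim = sim_config()))
  split_prefix <- function(prefix) {
    sel <- startsWith(names(kv), paste0(prefix, "."))
    res <- kv[sel]
    names(res) <- substring(names(res), nchar(prefix) + 2)
    res
  }
  link_kv <- split_prefix("link")
  qc_kv <- split_prefix("qc")
  sim_kv <- split_prefix("sim")
  top <- kv[!grepl("^(link|qc|sim)\\.", names(kv))]
  check_names <- function(got, allowed, where) {
    bad <- setdiff(names(got), allowed)
    if (length(bad)) stop("unknown ", where, " config key(s): ",
                          paste(bad, collapse = ", "))
  }
  check_names(link_kv, names(formals(link_params)), "link")
  check_names(qc_kv, names(formals(qc_params)), "qc")
  check_names(sim_kv, names(formals(sim_config)), "sim")
  check_names(top, setdiff(names(formals(pipeline_config)), c("link", "qc")), "pipeline")
  cfg <- do.call(pipeline_config, c(top, list(
    link = do.call(link_params, link_kv),
    qc = do.call(qc_params, qc_kv))))
  sim <- do.call(sim_config, sim_kv)
  list(config = cfg, sim = sim)
}
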