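# Lineage inheritance analysis: sister and mother-daughter pairs, division
# symmetry classes, matched spatiotemporal control pairs, and the
# inheritance panel comparing related-pair correlations against controls.

#' Enumerate sister and mother-daughter pairs
#'
#' Sisters are child pairs sharing a parent; mother-daughter pairs are each
#' (parent, child) pair. Only tracks present in the growth-summary table
#' (i.e. full-interphase trajectories) contribute.
#'
#' @param lineage Lineage table (`track_id, parent_id, family_id`).
#' @param summaries Growth-summary table with a `track_id` column.
#' @return List with `sisters` (`id1, id2`; `id1 < id2`) and
#'   `mother_daughter` (`mother_id, daughter_id`) data.tables.
#' @export
find_pairs <- function(lineage, summaries) {
  lin <- data.table::as.data.table(lineage)
  validate_lineage(lin)
  have <- unique(data.table::as.data.table(summaries)$track_id)
  kids <- lin[!is.na(parent_id)]
  md <- kids[track_id %in% have & parent_id %in% have,
             list(mother_id = parent_id, daughter_id = track_id)]
  sib <- kids[track_id %in% have]
  sis <- sib[, if (.N == 2) list(id1 = min(track_id), id2 = max(track_id)),
             by = parent_id]
  if (!nrow(sis)) {
    sis <- data.table::data.table(id1 = integer(0), id2 = integer(0),
                                  parent_id = integer(0))
  } else data.table::setcolorder(sis, c("id1", "id2", "parent_id"))
  list(sisters = sis[], mother_daughter = md[])
}

# row lookup of a summary table by track id
summary_row <- function(summaries, id) {
  s <- data.table::as.data.table(summaries)
  s[match(id, s$track_id)]
}

#' Combined sister starting volume as a fraction of the mother's ending volume
#'
#' For each sister pair whose mother also has a growth summary, the ratio
#' (d1_start + d2_start) / mother_end. The population mean of this ratio is
#' the division retention (study: 95.9 +/- 4.2\%), and the combined
#' starting volume correlates strongly with the mother's ending volume.
#'
#' @param sisters Sister-pair table from [find_pairs()] (needs `parent_id`).
#' @param summaries Growth-summary table.
#' @return List with `pairs` (per-pair ratios), `mean_ratio`, `sd_ratio`,
#'   `pearson_r` (combined start vs mother end), `n`.
#' @export
combined_start_ratio <- function(sisters, summaries) {
  s <- data.table::as.data.table(summaries)
  p <- data.table::as.data.table(sisters)
  p <- p[parent_id %in% s$track_id]
  if (!nrow(p)) return(list(pairs = p, mean_ratio = NA_real_,
                            sd_ratio = NA_real_, pearson_r = NA_real_, n = 0L))
  d1 <- summary_row(s, p$id1)$starting_volume
  d2 <- summary_row(s, p$id2)$starting_volume
  mend <- summary_row(s, p$parent_id)$ending_volume
  combined <- d1 + d2
  ratio <- combined / mend
  out <- data.table::data.table(p, combined_start = combined,
                                mother_end = mend, ratio = ratio)
  list(pairs = out,
       mean_ratio = mean(ratio), sd_ratio = sd(ratio),
       pearson_r = if (nrow(out) >= 3) cor(combined, mend) else NA_real_,
       n = nrow(out))
}

#' Classify sister pairs by division symmetry
#'
#' Strict thresholds on the absolute starting-volume difference: symmetric
#' below 30 um^3, asymmetric above 50 um^3, excluded in between (where the
#' difference could reflect transition-timing uncertainty rather than a
#' genuinely asymmetric division). Reports the pooled starting-volume CV
#' per class with a bootstrap 90\% CI.
#'
#' @param sisters Sister-pair table.
#' @param summaries Growth-summary table.
#' @param symmetric_max,asymmetric_min Class thresholds (defaults 30, 50).
#' @param n_boot Bootstrap resamples for the CV CIs (default 500).
#' @return List with `pairs` (labelled) and `class_cv` (per-class CV with
#'   CI bounds).
#' @export
classify_symmetry <- function(sisters, summaries, symmetric_max = 30,
                              asymmetric_min = 50, n_boot = 500) {
  s <- data.table::as.data.table(summaries)
  p <- data.table::as.data.table(sisters)
  v1 <- summary_row(s, p$id1)$starting_volume
  v2 <- summary_row(s, p$id2)$starting_volume
  dv <- abs(v1 - v2)
  label <- ifelse(dv < symmetric_max, "symmetric",
                  ifelse(dv > asymmetric_min, "asymmetric", "excluded"))
  pairs <- data.table::data.table(p, v1 = v1, v2 = v2, delta = dv,
                                  label = label)
  class_cv <- data.table::rbindlist(lapply(
    c("symmetric", "asymmetric"), function(cl) {
      vols <- c(pairs[label == cl]$v1, pairs[label == cl]$v2)
      if (length(vols) < 3)
        return(data.table::data.table(class = cl, cv = NA_real_,
                                      lower = NA_real_, upper = NA_real_,
                                      n_pairs = sum(label == cl)))
      ci <- bootstrap_stat_ci(vols, stat = cv, n_resamples = n_boot)
      data.table::data.table(class = cl, cv = ci$estimate, lower = ci$lower,
                             upper = ci$upper, n_pairs = sum(label == cl))
    }))
  list(pairs = pairs, class_cv = class_cv)
}

# pairing metadata required by the control matchers: birth time/position and
# division time/position per summarised track
.control_meta_cols <- c("track_id", "family_id", "birth_time_min", "birth_x",
                        "birth_y", "division_time_min", "division_x",
                        "division_y", "starting_volume", "ending_volume")

#' Pairing metadata for control matching
#'
#' Birth is the formation event (time and centroid at the formation frame);
#' division is the breakdown event. Positions fall back to the nearest
#' observed record within two frames of the event.
#'
#' @param trajs Named list of full-interphase trajectories.
#' @param summaries Growth-summary table.
#' @param frame_interval_min Minutes per frame.
#' @return `data.table` with one row per summarised track.
#' @export
control_metadata <- function(trajs, summaries, frame_interval_min = 5) {
  s <- data.table::as.data.table(summaries)
  pos_near <- function(t, frame) {
    d <- t$data
    cand <- which(!is.na(d$x) & abs(d$frame - frame) <= 2)
    if (!length(cand)) return(c(NA_real_, NA_real_))
    i <- cand[which.min(abs(d$frame[cand] - frame))]
    c(d$x[i], d$y[i])
  }
  rows <- lapply(s$track_id, function(id) {
    t <- trajs[[as.character(id)]]
    if (is.null(t)) return(NULL)
    bp <- pos_near(t, t$formation_frame)
    dp <- pos_near(t, t$breakdown_frame)
    data.table::data.table(
      track_id = id, family_id = t$family_id,
      birth_time_min = t$formation_frame * frame_interval_min,
      birth_x = bp[1], birth_y = bp[2],
      division_time_min = t$breakdown_frame * frame_interval_min,
      division_x = dp[1], division_y = dp[2],
      starting_volume = summary_row(s, id)$starting_volume,
      ending_volume = summary_row(s, id)$ending_volume)
  })
  data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
}

# greedy at-most-once matching: candidate pairs sorted by normalized
# mismatch; each track used in at most one control pair
greedy_match <- function(cand) {
  if (!nrow(cand)) return(cand)
  data.table::setorder(cand, mismatch)
  used <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- as.character(cand$id1[i]); b <- as.character(cand$id2[i])
    if (a %in% used || b %in% used) next
    keep[i] <- TRUE
    used <- c(used, a, b)
  }
  cand[keep]
}

#' Match control sister pairs
#'
#' Unrelated nuclei (different families) born at the same time (birth-time
#' gap strictly less than 10 minutes), the same place (birth distance
#' strictly less than 60 um), and with similar size (starting-volume
#' difference strictly less than 80 um^3). Each nucleus is used in at most
#' one control pair; candidates are taken greedily by smallest combined
#' normalized mismatch.
#'
#' @param meta Metadata from [control_metadata()].
#' @param max_birth_gap_min,max_birth_dist_um,max_start_diff Gate values
#'   (defaults 10, 60, 80; all strict inequalities).
#' @return `data.table` of control sister pairs (`id1, id2`, gaps,
#'   mismatch).
#' @export
match_control_sisters <- function(meta, max_birth_gap_min = 10,
                                  max_birth_dist_um = 60,
                                  max_start_diff = 80) {
  m <- data.table::as.data.table(meta)
  n <- nrow(m)
  if (n < 2) return(empty_pairs())
  idx <- t(utils::combn(n, 2))
  i <- idx[, 1]; j <- idx[, 2]
  unrelated <- is.na(m$family_id[i]) | is.na(m$family_id[j]) |
    m$family_id[i] != m$family_id[j]
  dt_gap <- abs(m$birth_time_min[i] - m$birth_time_min[j])
  dd <- sqrt((m$birth_x[i] - m$birth_x[j])^2 +
             (m$birth_y[i] - m$birth_y[j])^2)
  dv <- abs(m$starting_volume[i] - m$starting_volume[j])
  ok <- unrelated & dt_gap < max_birth_gap_min & dd < max_birth_dist_um &
    dv < max_start_diff & !is.na(dd)
  if (!any(ok)) return(empty_pairs())
  cand <- data.table::data.table(
    id1 = m$track_id[i[ok]], id2 = m$track_id[j[ok]],
    birth_gap_min = dt_gap[ok], birth_dist_um = dd[ok],
    start_diff = dv[ok],
    mismatch = dt_gap[ok] / max_birth_gap_min + dd[ok] / max_birth_dist_um +
      dv[ok] / max_start_diff)
  greedy_match(cand)
}

empty_pairs <- function() {
  data.table::data.table(id1 = integer(0), id2 = integer(0),
                         birth_gap_min = numeric(0),
                         birth_dist_um = numeric(0),
                         start_diff = numeric(0), mismatch = numeric(0))
}

#' Match control mother-daughter pairs
#'
#' Unrelated (control mother, control daughter) pairs where the daughter
#' candidate is born strictly within 60 minutes and 60 um of the mother
#' candidate's division (breakdown) time and location, and the daughter's
#' starting volume is strictly within 60 um^3 of half the mother's ending
#' volume. At-most-once greedy matching as for control sisters.
#'
#' @param meta Metadata from [control_metadata()].
#' @param max_time_gap_min,max_dist_um,max_half_end_diff Gate values
#'   (defaults 60, 60, 60; strict inequalities).
#' @return `data.table` of pairs (`mother_id, daughter_id`, gaps,
#'   mismatch).
#' @export
match_control_mother_daughter <- function(meta, max_time_gap_min = 60,
                                          max_dist_um = 60,
                                          max_half_end_diff = 60) {
  m <- data.table::as.data.table(meta)
  n <- nrow(m)
  if (n < 2) return(data.table::data.table(mother_id = integer(0),
                                           daughter_id = integer(0)))
  gi <- rep(seq_len(n), each = n)   # mother candidate
  gj <- rep(seq_len(n), times = n)  # daughter candidate
  sel <- gi != gj
  gi <- gi[sel]; gj <- gj[sel]
  unrelated <- is.na(m$family_id[gi]) | is.na(m$family_id[gj]) |
    m$family_id[gi] != m$family_id[gj]
  dt_gap <- abs(m$birth_time_min[gj] - m$division_time_min[gi])
  dd <- sqrt((m$birth_x[gj] - m$division_x[gi])^2 +
             (m$birth_y[gj] - m$division_y[gi])^2)
  dv <- abs(m$starting_volume[gj] - m$ending_volume[gi] / 2)
  ok <- unrelated & dt_gap < max_time_gap_min & dd < max_dist_um &
    dv < max_half_end_diff & !is.na(dd)
  if (!any(ok)) return(data.table::data.table(mother_id = integer(0),
                                              daughter_id = integer(0)))
  cand <- data.table::data.table(
    id1 = m$track_id[gi[ok]], id2 = m$track_id[gj[ok]],
    time_gap_min = dt_gap[ok], dist_um = dd[ok], half_end_diff = dv[ok],
    mismatch = dt_gap[ok] / max_time_gap_min + dd[ok] / max_dist_um +
      dv[ok] / max_half_end_diff)
  res <- greedy_match(cand)
  data.table::setnames(res, c("id1", "id2"), c("mother_id", "daughter_id"))
  res[]
}

# order-symmetrized paired feature values for sister-type pairs: each pair
# contributes both orderings so the correlation is member-order invariant
symmetrized_xy <- function(v1, v2) {
  list(x = c(v1, v2), y = c(v2, v1))
}

#' Inheritance panel: related-pair vs control-pair correlations
#'
#' For each growth feature, the Pearson correlation within true pairs and
#' within matched control pairs, with bootstrap 90\% CIs (pairs are
#' resampled; sister-type correlations are computed on the
#' order-symmetrized set). A feature is flagged inherited when the true and
#' control CIs do not overlap.
#'
#' @param true_pairs Two-column id table of related pairs.
#' @param control_pairs Two-column id table of matched controls.
#' @param summaries Growth-summary table.
#' @param features Feature columns to compare (default the six growth
#'   features).
#' @param symmetric Logical: are the pairs unordered (sisters) so the
#'   correlation must be order-symmetrized? (default TRUE; use FALSE for
#'   mother-daughter pairs).
#' @param n_boot Bootstrap resamples (default 500).
#' @param min_pairs Minimum pairs per group (default 10).
#' @return `data.table`: feature, group r and CI bounds, n, and
#'   `inherited`.
#' @export
inheritance_panel <- function(true_pairs, control_pairs, summaries,
                              features = c("starting_volume", "ending_volume",
                                           "growth_duration_h", "growth_rate",
                                           "fold_change", "alpha"),
                              symmetric = TRUE, n_boot = 500,
                              min_pairs = 10L) {
  s <- data.table::as.data.table(summaries)
  get_vals <- function(pairs, feat) {
    ids <- as.matrix(pairs[, 1:2])
    v1 <- s[[feat]][match(ids[, 1], s$track_id)]
    v2 <- s[[feat]][match(ids[, 2], s$track_id)]
    ok <- !is.na(v1) & !is.na(v2)
    list(v1 = v1[ok], v2 = v2[ok])
  }
  pair_corr <- function(v1, v2) {
    if (symmetric) {
      sxy <- symmetrized_xy(v1, v2)
      cor(sxy$x, sxy$y)
    } else cor(v1, v2)
  }
  boot_ci <- function(v1, v2) {
    n <- length(v1)
    rs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      a <- v1[idx]; bb <- v2[idx]
      if (sd(a) == 0 || sd(bb) == 0) return(NA_real_)
      pair_corr(a, bb)
    }, numeric(1))
    quantile(rs[!is.na(rs)], c(0.05, 0.95), names = FALSE)
  }
  rows <- lapply(features, function(f) {
    tv <- get_vals(true_pairs, f)
    cvv <- get_vals(control_pairs, f)
    if (length(tv$v1) < min_pairs || length(cvv$v1) < min_pairs) {
      warning("skipping feature ", f, ": fewer than ", min_pairs,
              " usable pairs in a group")
      return(NULL)
    }
    ci_t <- boot_ci(tv$v1, tv$v2)
    ci_c <- boot_ci(cvv$v1, cvv$v2)
    data.table::data.table(
      feature = f,
      r_true = pair_corr(tv$v1, tv$v2), true_lower = ci_t[1],
      true_upper = ci_t[2], n_true = length(tv$v1),
      r_control = pair_corr(cvv$v1, cvv$v2), control_lower = ci_c[1],
      control_upper = ci_c[2], n_control = length(cvv$v1),
      inherited = ci_t[1] > ci_c[2] || ci_t[2] < ci_c[1])
  })
  data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
}
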