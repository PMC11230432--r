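# tracking: assignment linking, track building, gap closing; the oracle is
# exhaustive enumeration of all matchings including birth/death options

test_that("simple links behave as expected", {
  a <- frame_detections(0L, 1L, x = 10, y = 10, volume = 500)
  b <- frame_detections(1L, 1L, x = 10, y = 10, volume = 500)
  l <- link_frames(a, b)
  expect_equal(nrow(l), 1)
  expect_equal(l$cost, 0)

  empty <- frame_detections(1L, integer(0), x = numeric(0), y = numeric(0),
                            volume = numeric(0))
  expect_equal(nrow(link_frames(a, empty)), 0)
  expect_error(link_frames(a, frame_detections(5L, 1L, 0, 0,
                                               volume = 500)),
               "consecutive")
})

test_that("assignment equals the exhaustive minimum (cyclic 3-shift)", {
  p <- link_params()
  ang <- seq(0, 2 * pi, length.out = 4)[1:3]
  a <- frame_detections(0L, 1:3, x = 5 * cos(ang), y = 5 * sin(ang),
                        volume = c(500, 520, 540))
  # positions cyclically shifted; all pairwise distances < max
  b <- frame_detections(1L, 1:3, x = 5 * cos(ang + 2), y = 5 * sin(ang + 2),
                        volume = c(505, 525, 545))
  cost <- nucgrowth:::link_cost_matrix(a, b, p)
  links <- link_frames(a, b, p)
  expect_equal(links_total_cost(links, a, b, p),
               bf_min_matching_cost(cost, p$birth_death_cost),
               tolerance = 1e-10)
})

test_that("assignment equals the exhaustive minimum on random instances", {
  p <- link_params()
  set.seed(12)
  for (rep in 1:20) {
    na <- sample(0:6, 1); nb <- sample(0:6, 1)
    a <- frame_detections(0L, seq_len(na), x = runif(na, 0, 30),
                          y = runif(na, 0, 30),
                          volume = runif(na, 400, 650))
    b <- frame_detections(1L, seq_len(nb), x = runif(nb, 0, 30),
                          y = runif(nb, 0, 30),
                          volume = runif(nb, 400, 650))
    links <- link_frames(a, b, p)
    if (!na || !nb) { expect_equal(nrow(links), 0); next }
    cost <- nucgrowth:::link_cost_matrix(a, b, p)
    expect_equal(links_total_cost(links, a, b, p),
                 bf_min_matching_cost(cost, p$birth_death_cost),
                 tolerance = 1e-10)
  }
})

test_that("tracks are recovered perfectly for slow drift without division", {
  set.seed(7)
  n <- 8; n_frames <- 30
  x0 <- runif(n, 0, 120); y0 <- runif(n, 0, 120)
  vol <- runif(n, 450, 650)
  frames <- lapply(0:(n_frames - 1), function(f) {
    frame_detections(f, seq_len(n),
                     x = x0 + cumsum(rep(0.4, f + 1))[f + 1] + rnorm(n, 0, 0.3),
                     y = y0 + rnorm(n, 0, 0.3),
                     volume = vol * (1 + 0.001 * f))
  })
  tracks <- build_tracks(frames)
  expect_equal(length(unique(tracks$track_id)), n)
  # purity and completeness: each track contains one detection id throughout
  purity <- tracks[, list(ok = length(unique(detection_id)) == 1 &&
                            .N == n_frames), by = track_id]
  expect_true(all(purity$ok))
})

test_that("jumps beyond the distance gate end tracks, no false crossing", {
  # both nuclei move further than max_link_distance: all links inadmissible
  a <- frame_detections(0L, 1:2, x = c(0, 40), y = 0, volume = c(500, 500))
  b <- frame_detections(1L, 1:2, x = c(100, 140), y = 0,
                        volume = c(500, 500))
  tracks <- build_tracks(list(a, b))
  expect_equal(length(unique(tracks$track_id)), 4)

  # exact position swap of clearly different-sized nuclei: the spatially
  # tempting crossing is vetoed by the volume gate, so both tracks end
  a2 <- frame_detections(0L, 1:2, x = c(0, 40), y = 0, volume = c(450, 700))
  b2 <- frame_detections(1L, 1:2, x = c(40, 0), y = 0, volume = c(450, 700))
  tracks2 <- build_tracks(list(a2, b2))
  expect_equal(length(unique(tracks2$track_id)), 4)
})

test_that("single frame input gives one 1-frame track per detection", {
  a <- frame_detections(0L, 1:3, x = c(0, 10, 20), y = 0,
                        volume = c(500, 510, 520))
  tracks <- build_tracks(list(a))
  expect_equal(nrow(tracks), 3)
  expect_equal(length(unique(tracks$track_id)), 3)
})

test_that("unsorted frames are rejected", {
  a <- frame_detections(0L, 1L, 0, 0, volume = 500)
  b <- frame_detections(1L, 1L, 0, 0, volume = 500)
  expect_error(build_tracks(list(b, a)), "sorted")
})

test_that("gap closing bridges 1-frame dropouts but not 4-frame gaps", {
  mk_frames <- function(skip) {
    lapply(0:11, function(f) {
      if (f %in% skip)
        return(frame_detections(f, integer(0), numeric(0), numeric(0),
                                volume = numeric(0)))
      frame_detections(f, 1L, x = f * 0.5, y = 0, volume = 500 + f)
    })
  }
  # delete one frame: merged into a single track with a gap record
  tracks <- close_gaps(build_tracks(mk_frames(5L)))
  expect_equal(length(unique(tracks$track_id)), 1)
  tr <- trajectories_from_table(
    tracks_to_feature_table(tracks))[[1]]
  expect_true(is.na(tr$data$volume[tr$data$frame == 5]))

  # delete four consecutive frames: stays two tracks
  tracks4 <- close_gaps(build_tracks(mk_frames(4:7)))
  expect_equal(length(unique(tracks4$track_id)), 2)
})

test_that("FOV-edge track ends are never used for gap closing", {
  frames <- lapply(0:9, function(f) {
    if (f %in% 4:5)
      return(frame_detections(f, integer(0), numeric(0), numeric(0),
                              volume = numeric(0)))
    frame_detections(f, 1L, x = f * 0.5, y = 0, volume = 500,
                     fov_edge = (f == 3)) # the end before the gap is at edge
  })
  tracks <- close_gaps(build_tracks(frames))
  expect_equal(length(unique(tracks$track_id)), 2)
})

test_that("no detection belongs to two tracks on simulator output", {
  sim <- small_sim()
  feat <- data.table::as.data.table(sim$features)[!is.na(volume)]
  feat <- feat[frame < 60]
  feat[, detection_id := seq_len(.N)]
  frames <- lapply(sort(unique(feat$frame)), function(f) {
    g <- feat[frame == f]
    frame_detections(f, g$detection_id, g$x, g$y, g$z, g$volume, g$fov_edge)
  })
  tracks <- close_gaps(build_tracks(frames))
  expect_false(anyDuplicated(tracks$detection_id) > 0)
})
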