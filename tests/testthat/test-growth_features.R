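# growth features: transition detection, normalized time, power-law fits,
# transient rates, growth summaries

test_that("transition detection matches the two-segment oracle on a kink", {
  t_min <- seq(0, 195, by = 5)
  v <- ifelse(t_min <= 30, 500 + 2 * t_min, 560 + 0.3 * (t_min - 30))
  fit <- detect_transition(mk_traj(v))
  expect_true(fit$valid)
  oracle_frame <- bf_two_segment_breakpoint(t_min / 5, v)
  expect_lte(abs(fit$transition_frame - oracle_frame), 2)
  expect_lte(abs(fit$transition_frame - 6), 2)
  # center is the asymptote intersection
  m1 <- fit$asymptote1["slope"]; c1 <- fit$asymptote1["intercept"]
  m2 <- fit$asymptote2["slope"]; c2 <- fit$asymptote2["intercept"]
  expect_equal(unname(m1 * fit$center["x"] + c1),
               unname(fit$center["y"]), tolerance = 1e-8)
  expect_equal(unname(m2 * fit$center["x"] + c2),
               unname(fit$center["y"]), tolerance = 1e-8)
})

test_that("an exactly linear trajectory has no valid transition", {
  fit <- detect_transition(mk_traj(500 + seq(0, 195, 5)))
  expect_false(fit$valid)
  expect_true(is.na(fit$transition_frame))
})

test_that("transition detection is invariant to rescaling volume and time", {
  t_min <- seq(0, 195, by = 5)
  v <- ifelse(t_min <= 40, 400 + 3 * t_min, 520 + 0.5 * (t_min - 40))
  f1 <- detect_transition(mk_traj(v))
  f2 <- detect_transition(mk_traj(v * 1000))
  expect_equal(f1$transition_frame, f2$transition_frame)
})

test_that("transitions are recovered within 2 frames on 200 synthetic tracks", {
  set.seed(5)
  errs <- vapply(1:200, function(i) {
    v0 <- rnorm(1, 517.9, 54.9)
    te <- max(rnorm(1, 38, 10), 10)
    tg <- max(rnorm(1, 14.9, 1.9), 6)
    al <- min(max(rnorm(1, 1.15, 0.2), 0.5), 2)
    tr <- make_biphasic_trajectory(v0, te, tg, al, noise_frac = 0.0064)
    fit <- detect_transition(mk_traj(tr$volume))
    abs(fit$transition_frame - (tr$transition_index - 1L))
  }, numeric(1))
  expect_lte(mean(errs), 2)
})

test_that("normalized interphase time hits its endpoints", {
  tr <- mk_traj(rep(500, 181), frame0 = 10L, formation = 10L,
                breakdown = 190L)
  nt <- normalized_interphase_time(tr)
  expect_equal(nt[tr$data$frame == 10], 0)
  expect_equal(nt[tr$data$frame == 190], 1)
  expect_equal(nt[tr$data$frame == 100], 0.5)
  bad <- mk_traj(rep(500, 5)); bad$breakdown_frame <- bad$formation_frame
  expect_error(normalized_interphase_time(bad), "follow")
})

test_that("power-law fit is exact on noise-free closed forms", {
  th <- seq(0, 14, by = 5 / 60)
  lin <- mk_traj(500 + 10 * th); lin$transition_frame <- 0L
  pf <- fit_power_law(lin)
  expect_equal(pf$alpha, 1, tolerance = 1e-6)
  expect_equal(pf$r, 10, tolerance = 1e-6)
  expect_equal(pf$v_start_fit, 500, tolerance = 1e-6)

  sup <- mk_traj(500 + 5 * th^1.5); sup$transition_frame <- 0L
  pf2 <- fit_power_law(sup)
  expect_equal(pf2$alpha, 1.5, tolerance = 1e-3)

  flat <- mk_traj(rep(500, length(th))); flat$transition_frame <- 0L
  expect_false(fit_power_law(flat)$valid)
})

test_that("alpha recovery holds at 0.64% noise within 0.05", {
  set.seed(6)
  th <- seq(0, 14, by = 5 / 60)
  al <- replicate(20, {
    v <- (500 + 5 * th^1.5) * (1 + rnorm(length(th), 0, 0.0064))
    tr <- mk_traj(v); tr$transition_frame <- 0L
    fit_power_law(tr)$alpha
  })
  expect_lt(mean(abs(al - 1.5)), 0.05)
})

test_that("alpha fixed at 1 reduces to ordinary linear regression", {
  set.seed(7)
  th <- seq(0, 10, by = 5 / 60)
  v <- 480 + 23 * th + rnorm(length(th), 0, 4)
  tr <- mk_traj(v); tr$transition_frame <- 0L
  pf <- fit_power_law(tr, alpha_bounds = c(1, 1))
  ref <- lm(v ~ th)
  expect_equal(pf$v_start_fit, unname(coef(ref)[1]), tolerance = 1e-9)
  expect_equal(pf$r, unname(coef(ref)[2]), tolerance = 1e-9)
})

test_that("transient rates follow the centered-difference closed forms", {
  # linear volume, slope 1 um^3/min -> 60 um^3/h everywhere valid
  n <- 241
  lin <- mk_traj(500 + (seq_len(n) - 1) * 5)
  rs <- transient_growth_rate(lin)
  expect_true(all(abs(rs$rate[rs$valid] - 60) < 1e-9))

  # V = t^2 (t in hours): rate at t is exactly 2t
  tt_h <- (seq_len(n) - 1) * 5 / 60
  sq <- mk_traj(tt_h^2)
  rs2 <- transient_growth_rate(sq)
  t5 <- which(rs2$time_min == 300)
  expect_equal(rs2$rate[t5], 10, tolerance = 1e-9)
  valid_t <- rs2$time_min[rs2$valid] / 60
  expect_equal(rs2$rate[rs2$valid], 2 * valid_t, tolerance = 1e-9)

  # trimming: earlier than 2 h after formation is missing
  t90 <- which(rs2$time_min == 90)
  expect_true(is.na(rs2$rate[t90]))
  # within 30 min of breakdown is missing
  expect_true(is.na(rs2$rate[rs2$time_min == (n - 1) * 5 - 25]))
})

test_that("trapezoidal integral of rates recovers the volume change", {
  tr <- make_biphasic_trajectory(500, 40, 15, 1.3, noise_frac = 0,
                                 added_volume = 520)
  t1 <- mk_traj(tr$volume)
  rs <- transient_growth_rate(t1)
  sel <- which(rs$valid)
  t_h <- rs$time_min[sel] / 60
  integral <- sum(diff(t_h) * (head(rs$rate[sel], -1) + tail(rs$rate[sel], -1)) / 2)
  truth <- t1$data$volume[sel[length(sel)]] - t1$data$volume[sel[1]]
  expect_equal(integral, truth, tolerance = 0.01 * abs(truth))
})

test_that("early/late rate means follow their definitions", {
  mk_series <- function(rate) {
    structure(list(rate = rate, valid = !is.na(rate),
                   time_min = seq_along(rate) * 5), class = "ng_rate_series")
  }
  const <- early_late_rates(mk_series(rep(4, 50)))
  expect_equal(const$difference, 0)
  lin <- early_late_rates(mk_series(as.numeric(1:100)))
  expect_equal(lin$early_mean, 15.5)
  expect_equal(lin$late_mean, 88)
  expect_equal(lin$difference, 72.5)
})

test_that("rate difference correlates with true alpha across tracks", {
  set.seed(8)
  res <- t(vapply(1:200, function(i) {
    al <- runif(1, 0.7, 1.8)
    tr <- make_biphasic_trajectory(520, 38, 15, al, noise_frac = 0.0064)
    t1 <- mk_traj(tr$volume)
    d <- early_late_rates(transient_growth_rate(t1))$difference
    c(al, d)
  }, numeric(2)))
  expect_gt(cor(res[, 1], res[, 2]), 0.7)
})

test_that("growth summaries match hand computation", {
  tr <- mk_traj(seq(500, 1000, length.out = 121))
  tr$transition_frame <- 0L
  gs <- growth_summary(tr, alpha = NA)
  expect_equal(gs$starting_volume, 500)
  expect_equal(gs$ending_volume, 1000)
  expect_equal(gs$added_volume, 500)
  expect_equal(gs$fold_change, 2)
  expect_equal(gs$growth_duration_h, 10)
  expect_equal(gs$growth_rate, 50)

  # three-track toy vs hand numbers
  toy <- list(
    a = { t <- mk_traj(seq(400, 900, length.out = 121)); t$transition_frame <- 0L; t },
    b = { t <- mk_traj(seq(600, 1080, length.out = 145)); t$transition_frame <- 0L; t },
    c = { t <- mk_traj(seq(500, 950, length.out = 133)); t$transition_frame <- 0L; t })
  gs3 <- growth_summaries(toy)
  expect_equal(gs3$added_volume, c(500, 480, 450))
  expect_equal(gs3$fold_change, c(900 / 400, 1080 / 600, 950 / 500))
  expect_equal(gs3$growth_duration_h, c(10, 12, 11))
  # identity: added = ending - starting, exactly
  expect_identical(gs3$added_volume, gs3$ending_volume - gs3$starting_volume)
})

test_that("population fold-change doubles on simulator defaults", {
  fix <- population_fixture()
  expect_gt(nrow(fix$summaries), 100)
  expect_true(mean(fix$summaries$fold_change) > 1.9 &&
                mean(fix$summaries$fold_change) < 2.1)
  # peak of the distribution (KDE mode) is near 2 as well
  expect_equal(density_mode(fix$summaries$fold_change), 2.05,
               tolerance = 0.15 / 2.05)
})
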