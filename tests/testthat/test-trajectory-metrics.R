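test_that("mean speed follows hand arithmetic and handles gaps", {
  tr <- trajectory(cbind(c(0, 0), c(0, 4)), frame_interval = 10)
  expect_equal(mean_speed(tr), 0.4)
  tr3 <- trajectory(cbind(c(0, 1, 3, 6), c(0, 0, 0, 0)), frame_interval = 10)
  expect_equal(mean_speed(tr3), mean(c(1, 2, 3) / 10))  # 0.2
  still <- trajectory(matrix(0, 5, 2), frame_interval = 10)
  expect_equal(mean_speed(still), 0)
  # a 2-frame gap uses the true elapsed 20 min, not 10
  gap <- trajectory(cbind(c(0, 1, 3), c(0, 0, 0)), frames = c(0, 1, 3),
                    frame_interval = 10)
  expect_equal(mean_speed(gap), mean(c(1 / 10, 2 / 20)))
})

test_that("mean speed is invariant under rigid rotation and translation", {
  set.seed(1)
  tr <- simulate_brownian_track(sim_config(n_steps = 30), 2)
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- trajectory(sweep(tr$positions %*% Rm, 2, c(5, -3), "+"),
                      frame_interval = tr$frame_interval)
  expect_equal(mean_speed(moved), mean_speed(tr), tolerance = 1e-12)
})

test_that("persistence matches geometry and stays in [0, 1]", {
  expect_equal(persistence(ballistic_track()), 1)
  loop <- trajectory(cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)),
                     frame_interval = 10)
  expect_equal(persistence(loop), 0)
  pyth <- trajectory(cbind(c(0, 3, 3), c(0, 0, 4)), frame_interval = 10)
  expect_equal(persistence(pyth), 5 / 7)
  still <- trajectory(matrix(0, 4, 2), frame_interval = 10)
  expect_equal(persistence(still), 0)  # 0/0 defined as 0
  set.seed(12)
  for (i in 1:50) {
    tr <- simulate_brownian_track(sim_config(n_steps = 40), 3)
    p <- persistence(tr)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("static classification is a strict path-length threshold", {
  params <- analysis_params()
  expect_equal(params$static_threshold, 75)
  mk <- function(total) trajectory(cbind(c(0, total), c(0, 0)),
                                   frame_interval = 10)
  expect_true(classify_static(mk(74.9), params))
  expect_false(classify_static(mk(75), params))      # ties are motile
  expect_true(classify_static(trajectory(matrix(0, 3, 2)), params))
  # raising the threshold never decreases the static count
  set.seed(4)
  tracks <- lapply(1:30, function(i)
    simulate_brownian_track(sim_config(n_steps = 50), 2))
  frac <- sapply(c(25, 75, 150), function(thr)
    mean(sapply(tracks, classify_static,
                params = analysis_params(static_threshold = thr))))
  expect_true(all(diff(frac) >= 0))
})

test_that("MSD curve reproduces closed forms and respects gaps", {
  lax <- analysis_params(max_lag = 2, min_pairs = 1)
  tr <- trajectory(cbind(c(0, 1, 2), c(0, 0, 0)), frame_interval = 10)
  m <- msd_curve(tr, lax)
  expect_equal(m$msd, c(1, 4))
  v <- 0.3; dt <- 10
  ball <- trajectory(cbind((0:19) * v * dt, 0), frame_interval = dt)
  mb <- msd_curve(ball, analysis_params(max_lag = 5, min_pairs = 1))
  expect_equal(mb$msd, (v * mb$lag_min)^2, tolerance = 1e-12)
  still <- trajectory(matrix(0, 12, 2))
  expect_true(all(msd_curve(still)$msd == 0))
  # pairs straddling a missing frame are excluded, not interpolated
  gap <- trajectory(cbind(c(0, 1, 5), c(0, 0, 0)), frames = c(0, 1, 3),
                    frame_interval = 10)
  mg <- msd_curve(gap, analysis_params(max_lag = 3, min_pairs = 1))
  expect_equal(mg$lag_frames, c(1, 2, 3))
  expect_equal(mg$n_pairs, c(1L, 1L, 1L))  # lag 1: (0,1); lag 2: (1,3); lag 3: (0,3)
  expect_equal(mg$msd, c(1, 16, 25))
  # too-short track flags undefined instead of erroring
  short <- trajectory(cbind(c(0, 1), c(0, 0)))
  expect_true(attr(msd_curve(short), "undefined"))
})

test_that("alpha exponent: ballistic closed form, scale invariance, NA rules", {
  ball <- ballistic_track(n = 40)
  expect_equal(alpha_exponent(msd_curve(ball)), 2, tolerance = 1e-6)
  scaled <- trajectory(ball$positions * 37.3, frame_interval = 10)
  expect_equal(alpha_exponent(msd_curve(scaled)),
               alpha_exponent(msd_curve(ball)), tolerance = 1e-9)
  still <- trajectory(matrix(0, 20, 2))
  expect_true(is.na(alpha_exponent(msd_curve(still))))  # all-zero MSD dropped
})

test_that("per-track metrics integrate the four measures coherently", {
  ball <- ballistic_track(n = 11, v = 0.1)  # 10 steps of 1 um
  tm <- compute_track_metrics(ball)
  expect_equal(tm$path_length, 10)
  expect_equal(tm$net_displacement, 10)
  expect_equal(tm$persistence, 1)
  expect_true(tm$is_static)  # 10 um < 75 um
  still <- trajectory(matrix(0, 20, 2))
  ts <- compute_track_metrics(still)
  expect_equal(ts$mean_speed, 0)
  expect_equal(ts$persistence, 0)
  expect_true(ts$is_static)
  expect_true(is.na(ts$alpha))
  set.seed(7)
  for (i in 1:25) {
    tm_i <- compute_track_metrics(simulate_brownian_track(sim_config(n_steps = 30), 2))
    expect_lte(tm_i$net_displacement, tm_i$path_length + 1e-12)
  }
  # short tracks keep speed/static but drop alpha
  short <- trajectory(cbind(c(0, 50, 100), c(0, 0, 0)), frame_interval = 10)
  expect_true(is.na(compute_track_metrics(short)$alpha))
})

test_that("cohort summary aggregates as the condition table expects", {
  set.seed(8)
  tracks <- c(
    lapply(1:8, function(i) simulate_persistent_track(sim_config(), 0.4, 2)),
    lapply(1:2, function(i) simulate_persistent_track(sim_config(), 0.001, 2)))
  mets <- cohort_metrics(tracks)
  summ <- summarize_cohort(mets, "1 mg/mL")
  expect_equal(summ$n_tracks, 10)
  expect_equal(summ$percent_static, 20)
  expect_equal(summ$mean_instant_speed, mean(mets$mean_speed))
  expect_equal(summ$percent_persistence, 100 * mean(mets$persistence))
  expect_true(summ$percent_static >= 0 && summ$percent_static <= 100)
  # all alpha undefined leaves the rest intact
  stills <- lapply(1:3, function(i) trajectory(matrix(0, 20, 2)))
  s2 <- summarize_cohort(cohort_metrics(stills), "x")
  expect_true(is.na(s2$mean_alpha))
  expect_equal(s2$percent_static, 100)
  expect_error(summarize_cohort(data.frame()), "at least one")
})

test_that("fBm cohorts recover alpha = 2 * hurst across the subdiffusive range", {
  set.seed(99)
  for (h in c(0.3, 0.75)) {
    a <- fbm_mean_alpha(150, h)
    expect_lt(abs(a - 2 * h), 0.1)
  }
})
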