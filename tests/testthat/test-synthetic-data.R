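test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_steps = 1), "n_steps")
  expect_error(sim_config(frame_interval = 0), "frame_interval")
  expect_error(sim_config(pixel_size = -1), "pixel_size")
  cfg <- sim_config(voxel_size = 0.5)
  expect_equal(cfg$voxel_size, c(0.5, 0.5, 0.5))
})

test_that("brownian tracks honour degenerate and determinism contracts", {
  cfg <- sim_config(seed = 11)
  still <- simulate_brownian_track(cfg, step_sigma = 0)
  expect_equal(path_length(still), 0)
  expect_true(all(still$positions == 0))
  expect_identical(simulate_brownian_track(cfg, 2)$positions,
                   simulate_brownian_track(cfg, 2)$positions)
  expect_error(simulate_brownian_track(cfg, -1), "step_sigma")
})

test_that("brownian ensemble MSD matches the analytic random-walk law", {
  # time-ensemble MSD over 1,000 tracks at lags 1..10 against the closed
  # form d * sigma^2 * tau (equivalently 2*d*D*tau with D = sigma^2 / 2)
  sigma <- 2
  set.seed(303)
  msd_sum <- numeric(10); n_sum <- numeric(10)
  for (i in 1:1000) {
    tr <- simulate_brownian_track(sim_config(n_steps = 64), sigma)
    m <- msd_curve(tr, analysis_params(max_lag = 10, min_pairs = 1))
    msd_sum <- msd_sum + m$msd * m$n_pairs
    n_sum <- n_sum + m$n_pairs
  }
  est <- msd_sum / n_sum
  theory <- 2 * sigma^2 * (1:10)
  expect_true(all(abs(est - theory) / theory < 0.05))
})

test_that("fBm tracks have the designed increment correlation and scaling", {
  # H = 0.5 reduces to Brownian: increments uncorrelated
  set.seed(42)
  cfg <- sim_config(n_steps = 144)
  R <- collmigr:::fbm_chol(143, 0.5)
  r1 <- replicate(400, {
    tr <- simulate_fbm_track(cfg, 0.5, chol_factor = R)
    dx <- diff(tr$positions[, 1])
    cor(dx[-length(dx)], dx[-1])
  })
  expect_lt(abs(mean(r1)), 0.05)
  expect_error(simulate_fbm_track(cfg, hurst = 1.2), "hurst")
  expect_error(simulate_fbm_track(cfg, hurst = 0), "hurst")
})

test_that("persistent walker spans the static-to-ballistic range", {
  cfg <- sim_config(seed = 5)
  expect_gt(persistence(simulate_persistent_track(cfg, 0.5, 1e6)), 0.99)
  static <- simulate_persistent_track(cfg, 0, 1)
  expect_true(classify_static(static, analysis_params(static_threshold = 1e-6)))
  set.seed(6)
  p0 <- mean(replicate(500, persistence(
    simulate_persistent_track(sim_config(), 0.5, 0))))
  expect_lt(p0, 0.25)  # uncorrelated 144-step walk
})

test_that("fiber field generator renders a verifiable ground truth", {
  cfg <- sim_config(seed = 21)
  blank <- generate_fiber_image(fiber_field_spec(n_fibers = 0, noise_sd = 1),
                                cfg)
  # no fibers: nothing above background + a few noise sd
  expect_equal(shg_positive_fraction(blank, threshold = 30), 0)
  expect_null(blank$segments)
  img <- generate_fiber_image(fiber_field_spec(n_fibers = 40), cfg)
  expect_equal(nrow(img$segments), 40)
  expect_identical(generate_fiber_image(fiber_field_spec(n_fibers = 40), cfg)$intensity,
                   img$intensity)
  expect_error(generate_fiber_image(fiber_field_spec(image_shape = c(8, 8))),
               "image_shape")
})

test_that("denser fiber fields shrink Lf; alignment raises anisotropy", {
  lf_sparse <- lf_dense <- aniso0 <- aniso20 <- numeric(8)
  for (s in 1:8) {
    cfg <- sim_config(seed = 500 + s)
    sparse <- generate_fiber_image(fiber_field_spec(n_fibers = 50), cfg)
    dense <- generate_fiber_image(fiber_field_spec(n_fibers = 500), cfg)
    lf_sparse[s] <- free_space_length(binarize_fibers(sparse, "fixed", 60))
    lf_dense[s] <- free_space_length(binarize_fibers(dense, "fixed", 60))
    iso <- generate_fiber_image(fiber_field_spec(orientation_kappa = 0), cfg)
    ali <- generate_fiber_image(fiber_field_spec(orientation_kappa = 20), cfg)
    aniso0[s] <- anisotropy_ellipse(fft_power_spectrum(iso))$anisotropy_ratio
    aniso20[s] <- anisotropy_ellipse(fft_power_spectrum(ali))$anisotropy_ratio
  }
  expect_true(all(lf_dense < lf_sparse))
  expect_true(all(aniso20 > aniso0))
})

test_that("cell phantom encodes its stated geometry", {
  truth <- phantom_truth(c(5, 10, 5))
  expect_equal(truth$semi_axes, c(10, 5, 5))  # sorted decreasing
  expect_equal(truth$true_volume, 4 / 3 * pi * 250, tolerance = 1e-12)
  expect_equal(truth$true_longitudinal, 20)
  cfg <- sim_config(seed = 31)
  ph <- generate_cell_phantom(truth, cfg)
  expect_identical(dim(ph$membrane), dim(ph$nucleus))
  # noiseless: membrane shell is hollow, nucleus solid, both bright
  expect_true(any(ph$membrane > 100) && any(ph$nucleus > 100))
  ctr <- (dim(ph$membrane) + 1) / 2
  expect_lt(ph$membrane[ctr[1], ctr[2], ctr[3]], 100)  # hollow centre
  expect_gt(ph$nucleus[ctr[1], ctr[2], ctr[3]], 100)
  expect_error(generate_cell_phantom(truth, cfg, dim = c(12, 12, 12)),
               "margin")
})

test_that("invasion depth sampler matches the truncated-exponential law", {
  expect_length(sample_invasion_depths(0, 250), 0)
  expect_identical(sample_invasion_depths(50, 250, 1000, seed = 9),
                   sample_invasion_depths(50, 250, 1000, seed = 9))
  d <- sample_invasion_depths(10000, 250, 1000, seed = 1)
  expect_true(all(d >= 0 & d <= 1000))
  # closed-form mean of Exp(1/250) truncated at 1000:
  # E[X | X <= M] = mu - M * exp(-M/mu) / (1 - exp(-M/mu))
  mu <- 250; M <- 1000
  theory <- mu - M * exp(-M / mu) / (1 - exp(-M / mu))
  expect_lt(abs(mean(d) - theory) / theory, 0.02)
})
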