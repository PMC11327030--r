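test_that("binarisation recovers a two-level image exactly and is batch-consistent", {
  truth <- matrix(FALSE, 32, 32); truth[10:20, 5:25] <- TRUE
  img <- fiber_image(matrix(10, 32, 32) + 190 * truth, pixel_size = 1)
  m_otsu <- binarize_fibers(img, "otsu")
  expect_identical(m_otsu$mask, truth)
  expect_warning(flat <- binarize_fibers(fiber_image(matrix(7, 20, 20), 1)),
                 "degenerate")
  expect_false(any(flat$mask))
  a <- binarize_fibers(img, "fixed", 100)
  b <- binarize_fibers(fiber_image(matrix(50, 32, 32), 1), "fixed", 100)
  expect_identical(a$threshold_used, b$threshold_used)
  expect_error(binarize_fibers(img, "fixed"), "fixed_threshold")
})

test_that("fiber length measurement matches known skeleton geometry", {
  m <- matrix(FALSE, 50, 60); m[25, 11:50] <- TRUE  # 40-px horizontal line
  lens <- measure_fiber_lengths(as_mask(m, pixel_size = 0.42), seed = 1)
  expect_length(lens, 1)
  expect_equal(lens, 40 * 0.42, tolerance = 0.42)  # +-1 px end effects
  # two disjoint segments, both measured when n_samples covers them
  m2 <- matrix(FALSE, 40, 40)
  m2[10, 5:14] <- TRUE; m2[30, 5:34] <- TRUE
  lens2 <- sort(measure_fiber_lengths(as_mask(m2), n_samples = 2, seed = 2,
                                      min_length = 0))
  expect_equal(lens2, c(10, 30), tolerance = 1)
  expect_identical(measure_fiber_lengths(as_mask(m2), 1, seed = 3),
                   measure_fiber_lengths(as_mask(m2), 1, seed = 3))
  expect_error(measure_fiber_lengths(as_mask(matrix(FALSE, 20, 20))),
               "no fiber")
})

test_that("deterministic Lf equals the dynamic-programming oracle", {
  expect_equal(free_space_length(as_mask(matrix(FALSE, 100, 100))), 100)
  expect_equal(free_space_length(as_mask(matrix(TRUE, 30, 30))), 0)
  line <- matrix(FALSE, 100, 100); line[, 31] <- TRUE
  expect_equal(free_space_length(as_mask(line)), 69)
  expect_equal(brute_force_lf(line), 69)
  set.seed(17)
  for (i in 1:40) {
    nr <- sample(8:48, 1); nc <- sample(8:48, 1)
    m <- matrix(runif(nr * nc) < runif(1, 0.01, 0.2), nr, nc)
    expect_equal(free_space_length(as_mask(m)), brute_force_lf(m))
  }
})

test_that("Lf is monotone under added fiber pixels and bounds its MC variant", {
  set.seed(18)
  m <- matrix(runif(60 * 60) < 0.02, 60, 60)
  lf0 <- free_space_length(as_mask(m))
  m2 <- m; m2[cbind(sample(60, 25, TRUE), sample(60, 25, TRUE))] <- TRUE
  expect_lte(free_space_length(as_mask(m2)), lf0)
  # the modal-count criterion can only stop earlier than the exact maximum
  for (i in 1:5) {
    m3 <- matrix(runif(50 * 50) < runif(1, 0.01, 0.1), 50, 50)
    det <- free_space_length(as_mask(m3))
    mc <- free_space_length(as_mask(m3), "monte_carlo", n_draws = 3000,
                            seed = i)
    expect_lte(mc, det)
  }
  # on structured masks dominated by their free space the two coincide:
  # a 6x6 fiber block in one corner leaves a 34-px free square whose empty
  # placements are the plurality outcome at the maximal side
  corner <- matrix(FALSE, 40, 40); corner[1:6, 1:6] <- TRUE
  expect_equal(free_space_length(as_mask(corner), "monte_carlo",
                                 n_draws = 5000, seed = 1),
               free_space_length(as_mask(corner)))
})

test_that("power spectrum obeys Parseval and locates stripe frequencies", {
  const <- fft_power_spectrum(matrix(5, 32, 32), window = "none")
  expect_lt(sum(const$power), 1e-18)
  set.seed(19)
  x <- matrix(rnorm(48 * 48), 48)
  ps <- fft_power_spectrum(x, window = "none")
  lhs <- sum((x - mean(x))^2)
  expect_equal(sum(ps$power) / ps$n_pixels, lhs, tolerance = 1e-6 * lhs)
  # vertical stripes of period 10 px: peaks on the horizontal frequency axis
  stripes <- matrix(0, 120, 120)
  stripes[, (0:119) %% 10 < 3] <- 200
  pv <- fft_power_spectrum(stripes, window = "none")
  peak <- which(pv$power == max(pv$power), arr.ind = TRUE)[1, ]
  expect_equal(abs(pv$fx[peak[2]]), 0.1, tolerance = 1e-9)
  expect_equal(pv$fy[peak[1]], 0, tolerance = 1e-9)
})

test_that("anisotropy ellipse reads orientation and rotation behaviour", {
  stripes <- matrix(0, 128, 128)
  stripes[(0:127) %% 10 < 3, ] <- 200  # horizontal stripes (vary along y)
  ps <- fft_power_spectrum(fiber_image(stripes, 1), window = "none")
  an <- anisotropy_ellipse(ps)
  expect_lt(abs(an$dominant_orientation), 5)  # fibers horizontal
  img <- generate_fiber_image(fiber_field_spec(orientation_kappa = 20),
                              sim_config(seed = 23))
  a1 <- anisotropy_ellipse(fft_power_spectrum(img))
  rot <- fiber_image(t(img$intensity)[, rev(seq_len(nrow(img$intensity)))],
                     img$pixel_size)
  a2 <- anisotropy_ellipse(fft_power_spectrum(rot))
  expect_equal(a2$anisotropy_ratio, a1$anisotropy_ratio, tolerance = 0.02)
  shift <- abs(a1$dominant_orientation - a2$dominant_orientation)
  expect_equal(min(shift, 180 - shift), 90, tolerance = 5)
  # degenerate: almost-empty spectrum
  an_flat <- anisotropy_ellipse(fft_power_spectrum(matrix(1, 32, 32),
                                                   window = "none"))
  expect_true(is.na(an_flat$anisotropy_ratio))
})

test_that("radial profile decomposes stripe patterns into pore and fiber size", {
  stripes <- matrix(0, 120, 120)
  stripes[(0:119) %% 10 < 3, ] <- 200
  ps <- fft_power_spectrum(fiber_image(stripes, 1), window = "none")
  rs <- radial_size_profile(ps, fiber_fraction = 0.3)
  expect_false(rs$undefined)
  expect_equal(rs$spacing, 10, tolerance = 0.5)
  expect_equal(rs$fiber_size, 3, tolerance = 0.2)
  expect_equal(rs$pore_size, 7, tolerance = 0.5)
  set.seed(24)
  noise <- fiber_image(matrix(rnorm(128 * 128, 50, 5), 128), 1)
  expect_true(radial_size_profile(fft_power_spectrum(noise), 0)$undefined)
})

test_that("denser paired fields report smaller pores", {
  pores <- sapply(1:6, function(s) {
    sapply(c(50, 500), function(nf) {
      img <- generate_fiber_image(fiber_field_spec(n_fibers = nf),
                                  sim_config(seed = 600 + s))
      msk <- binarize_fibers(img, "fixed", 60)
      radial_size_profile(fft_power_spectrum(img),
                          fiber_fraction = mean(msk$mask))$pore_size
    })
  })
  expect_true(mean(pores[2, ]) < mean(pores[1, ]))
})

test_that("SHG-positive fraction is plain threshold arithmetic", {
  expect_equal(shg_positive_fraction(matrix(200, 20, 20), 100), 100)
  expect_equal(shg_positive_fraction(matrix(0, 20, 20), 100), 0)
  half <- matrix(c(0, 200), 20, 20)
  expect_equal(shg_positive_fraction(half, 100), 50)
})
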