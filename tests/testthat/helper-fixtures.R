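# shared fixtures and independent oracles, built in code at test time

# wrap a logical matrix as a binary fiber mask
as_mask <- function(m, pixel_size = 1) {
  structure(list(mask = m, pixel_size = pixel_size, threshold_used = 1),
            class = "binary_fiber_mask")
}

# independent oracle for the largest empty square: the classic
# min-of-three-neighbours dynamic programme (a different algorithm from the
# package's binary-search / summed-area implementation)
brute_force_lf <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0L, nr, nc)
  best <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!m[i, j]) {
        s[i, j] <- if (i == 1L || j == 1L) 1L
                   else min(s[i - 1L, j], s[i, j - 1L], s[i - 1L, j - 1L]) + 1L
        if (s[i, j] > best) best <- s[i, j]
      }
    }
  }
  best
}

# straight-line trajectory along x
ballistic_track <- function(n = 20, v = 1, dt = 10) {
  trajectory(cbind(x = (0:(n - 1)) * v * dt, y = 0), frame_interval = dt)
}

# batch of per-track metric rows
cohort_metrics <- function(tracks, params = analysis_params()) {
  do.call(rbind, lapply(tracks, compute_track_metrics, params = params))
}

# mean fitted alpha over n fBm tracks of a given hurst (chol factor reused)
fbm_mean_alpha <- function(n, hurst, cfg = sim_config(),
                           params = analysis_params()) {
  R <- collmigr:::fbm_chol(cfg$n_steps - 1L, hurst)
  mean(vapply(seq_len(n), function(i) {
    tr <- simulate_fbm_track(cfg, hurst, chol_factor = R)
    alpha_exponent(msd_curve(tr, params))
  }, numeric(1)), na.rm = TRUE)
}
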