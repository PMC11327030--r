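#' Simulate a Brownian (random-walk) trajectory
#'
#' The null process of migration analysis: independent zero-mean Gaussian
#' increments per axis with standard deviation `step_sigma` per frame. Its
#' ensemble mean-squared displacement is `MSD(tau) = 2 * d * sigma^2 * tau`
#' (tau in frames, d dimensions), so the fitted anomalous-diffusion exponent
#' must recover alpha = 1.
#'
#' @param config A [sim_config()]; `n_steps` positions are returned, the
#'   first at the origin.
#' @param step_sigma Per-axis step standard deviation, um (>= 0).
#' @param dim 2 (default) or 3 spatial dimensions.
#' @param track_id Identifier for the resulting trajectory.
#' @return A [trajectory()].
#' @examples
#' tr <- simulate_brownian_track(sim_config(seed = 1), step_sigma = 2)
#' @export
simulate_brownian_track <- function(config, step_sigma, dim = 2,
                                    track_id = "brownian") {
  stopifnot(inherits(config, "sim_config"))
  if (step_sigma < 0) stop("`step_sigma` must be >= 0", call. = FALSE)
  maybe_seed(config)
  n <- config$n_steps
  inc <- matrix(rnorm((n - 1) * dim, sd = step_sigma), ncol = dim)
  pos <- rbind(0, apply(inc, 2, cumsum))
  trajectory(pos, frame_interval = config$frame_interval, track_id = track_id)
}

# fBm covariance Cholesky factor for times 1..m (frame units)
fbm_chol <- function(m, hurst) {
  t <- seq_len(m)
  h2 <- 2 * hurst
  cov <- 0.5 * (outer(t^h2, t^h2, "+") - abs(outer(t, t, "-"))^h2)
  chol(cov)
}

#' Simulate a fractional Brownian motion trajectory
#'
#' Each coordinate is exact fractional Brownian motion with Hurst exponent
#' `hurst`, generated by Cholesky factorisation of the fBm covariance
#' `C(s, t) = scale^2 / 2 * (s^2H + t^2H - |s - t|^2H)`. The ensemble MSD
#' grows as `tau^(2H)`, so these tracks provide a tunable ground-truth
#' anomalous-diffusion exponent `alpha = 2 * hurst` covering the
#' subdiffusive regime seen for cells confined in dense collagen.
#'
#' @param config A [sim_config()].
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param scale Step scale, um (the per-frame standard deviation).
#' @param dim 2 (default) or 3 spatial dimensions.
#' @param track_id Identifier.
#' @param chol_factor Optional precomputed upper-triangular factor from
#'   `fbm_chol(config$n_steps - 1, hurst)`; pass it when simulating large
#'   cohorts to avoid refactorising per track.
#' @return A [trajectory()].
#' @export
simulate_fbm_track <- function(config, hurst, scale = 1, dim = 2,
                               track_id = "fbm", chol_factor = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1)
    stop("`hurst` must lie strictly inside (0, 1)", call. = FALSE)
  maybe_seed(config)
  m <- config$n_steps - 1L
  R <- if (is.null(chol_factor)) fbm_chol(m, hurst) else chol_factor
  z <- matrix(rnorm(m * dim), nrow = m)
  pos <- rbind(0, scale * crossprod(R, z))
  trajectory(pos, frame_interval = config$frame_interval, track_id = track_id)
}

#' Simulate a persistent (correlated) random-walk trajectory
#'
#' Constant step length `speed * frame_interval`; the heading angle evolves
#' by von Mises-distributed turns with concentration `angular_kappa`.
#' `angular_kappa = 0` gives an uncorrelated 2D walk; large values approach
#' ballistic motion (persistence ratio near 1). Used to validate the
#' persistence statistic (net over total displacement).
#'
#' @param config A [sim_config()].
#' @param speed Speed, um/min (>= 0); `speed = 0` yields a static track.
#' @param angular_kappa von Mises turn concentration (>= 0).
#' @param track_id Identifier.
#' @return A 2D [trajectory()].
#' @export
simulate_persistent_track <- function(config, speed, angular_kappa,
                                      track_id = "persistent") {
  stopifnot(inherits(config, "sim_config"))
  if (speed < 0) stop("`speed` must be >= 0", call. = FALSE)
  if (angular_kappa < 0) stop("`angular_kappa` must be >= 0", call. = FALSE)
  maybe_seed(config)
  n <- config$n_steps
  step_len <- speed * config$frame_interval
  heading <- runif(1, 0, 2 * pi) +
    cumsum(c(0, rvonmises(n - 2, mu = 0, kappa = angular_kappa)))
  pos <- rbind(0, cbind(cumsum(step_len * cos(heading)),
                        cumsum(step_len * sin(heading))))
  trajectory(pos, frame_interval = config$frame_interval, track_id = track_id)
}

#' Sample invasion depths from a truncated exponential
#'
#' Draws cell depths (um below the gel top) from an exponential distribution
#' with the given mean, truncated to `[0, max_depth]` by rejection (so the
#' density keeps its analytic exponential shape on the support). The
#' exponential is a stand-in for the unknown real depth distribution; a
#' ~1,000-um gel is the default support.
#'
#' @param n_cells Number of cells (>= 0).
#' @param mean_depth Mean of the untruncated exponential, um (> 0).
#' @param max_depth Truncation depth, um (> 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_cells` depths in `[0, max_depth]`.
#' @examples
#' d <- sample_invasion_depths(100, mean_depth = 250, max_depth = 1000, seed = 1)
#' @export
sample_invasion_depths <- function(n_cells, mean_depth, max_depth = 1000,
                                   seed = NULL) {
  if (n_cells < 0) stop("`n_cells` must be >= 0", call. = FALSE)
  if (mean_depth <= 0 || max_depth <= 0)
    stop("`mean_depth` and `max_depth` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (n_cells == 0) return(numeric(0))
  out <- numeric(0)
  rate <- 1 / mean_depth
  while (length(out) < n_cells) {
    draw <- rexp(max(n_cells, 2 * (n_cells - length(out))), rate = rate)
    out <- c(out, draw[draw <= max_depth])
  }
  out[seq_len(n_cells)]
}
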