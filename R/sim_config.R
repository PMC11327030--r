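#' Simulation configuration
#'
#' Bundles the acquisition-style parameters shared by all synthetic-data
#' generators. The defaults mirror a 24-h time-lapse recorded at one frame
#' every 10 minutes (144 frames), which is the standard protocol for
#' long-term single-cell migration assays in collagen gels.
#'
#' @param n_steps Number of positions per simulated track (default 144,
#'   i.e. 24 h at 10-min frames).
#' @param frame_interval Time between frames, minutes (default 10).
#' @param seed Integer seed; when non-`NULL` every generator call is
#'   bit-reproducible. `NULL` leaves the current RNG stream untouched.
#' @param pixel_size Pixel size for 2D images, um/pixel (default 0.42, a
#'   typical multiphoton pixel pitch).
#' @param voxel_size Voxel size for 3D images, um per axis, length-3
#'   (x, y, z); default 1 um isotropic.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' tr <- simulate_brownian_track(cfg, step_sigma = 2)
#' @export
sim_config <- function(n_steps = 144, frame_interval = 10, seed = NULL,
                       pixel_size = 0.42, voxel_size = c(1, 1, 1)) {
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 2)
    stop("`n_steps` must be a single number >= 2", call. = FALSE)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be > 0", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be > 0", call. = FALSE)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive values", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(n_steps = as.integer(n_steps), frame_interval = frame_interval,
         seed = seed, pixel_size = pixel_size, voxel_size = voxel_size),
    class = "sim_config"
  )
}

#' Fiber-field specification
#'
#' Describes a synthetic 2D fiber image: straight fiber segments with
#' Gaussian-distributed lengths and von Mises-distributed axis orientations,
#' rendered over a noisy background. Denser collagen gels are emulated by
#' more, shorter, less aligned fibers (see [collagen_condition_spec()]).
#'
#' @param image_shape Image size in pixels, `c(rows, cols)`; at least 16x16.
#' @param n_fibers Number of fiber segments (>= 0).
#' @param mean_length,length_sd Fiber length distribution, um (Gaussian,
#'   resampled to stay positive).
#' @param width Fiber width, um (> 0).
#' @param orientation_kappa von Mises concentration of the fiber axis angle;
#'   0 = isotropic, large = aligned.
#' @param background_level,fiber_level Background intensity and the additive
#'   intensity contributed by one fiber.
#' @param noise_sd Gaussian noise standard deviation, intensity units.
#' @param saturation Intensity ceiling applied after additive rendering.
#'
#' @return An object of class `fiber_field_spec`.
#' @export
fiber_field_spec <- function(image_shape = c(256, 256), n_fibers = 100,
                             mean_length = 20, length_sd = 5, width = 1.2,
                             orientation_kappa = 0, background_level = 10,
                             fiber_level = 120, noise_sd = 4,
                             saturation = 255) {
  if (length(image_shape) != 2 || any(image_shape < 16))
    stop("`image_shape` must be two values, each >= 16", call. = FALSE)
  if (n_fibers < 0) stop("`n_fibers` must be >= 0", call. = FALSE)
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (orientation_kappa < 0) stop("`orientation_kappa` must be >= 0", call. = FALSE)
  if (mean_length <= 0) stop("`mean_length` must be > 0", call. = FALSE)
  structure(
    list(image_shape = as.integer(image_shape), n_fibers = as.integer(n_fibers),
         mean_length = mean_length, length_sd = length_sd, width = width,
         orientation_kappa = orientation_kappa,
         background_level = background_level, fiber_level = fiber_level,
         noise_sd = noise_sd, saturation = saturation),
    class = "fiber_field_spec"
  )
}

#' Fiber-field presets emulating collagen gel densities
#'
#' Maps a collagen concentration (1, 3 or 6 mg/mL) to a [fiber_field_spec()]
#' that reproduces the direction of the density effects seen in collagen
#' gels: higher concentration gives more and shorter fibers, smaller pores
#' and weaker alignment. The mean fiber lengths follow the 33 / 16 / 8 um
#' progression measured across those gel densities; fiber counts and
#' orientation concentrations are the package's own stated world (see the
#' methods vignette) and are used as trend templates, not numeric targets.
#'
#' @param concentration One of 1, 3 or 6 (mg/mL).
#' @param image_shape Image size in pixels (default 256 x 256; at a 0.42
#'   um pixel this is a ~108-um field of view).
#' @return A `fiber_field_spec`.
#' @examples
#' spec <- collagen_condition_spec(6)
#' img <- generate_fiber_image(spec, sim_config(seed = 7))
#' @export
collagen_condition_spec <- function(concentration = c(1, 3, 6),
                                    image_shape = c(256, 256)) {
  concentration <- match.arg(as.character(concentration[1]), c("1", "3", "6"))
  # fiber area scales with collagen mass: n * length * width is roughly
  # proportional to concentration, while individual fibers shorten and
  # alignment degrades as the gel gets denser
  pars <- switch(concentration,
    "1" = list(n_fibers = 28,  mean_length = 33, length_sd = 8, width = 1.2,
               kappa = 4),
    "3" = list(n_fibers = 150, mean_length = 16, length_sd = 4, width = 1.0,
               kappa = 1),
    "6" = list(n_fibers = 500, mean_length = 8,  length_sd = 2, width = 0.9,
               kappa = 0.2))
  fiber_field_spec(image_shape = image_shape, n_fibers = pars$n_fibers,
                   mean_length = pars$mean_length, length_sd = pars$length_sd,
                   width = pars$width, orientation_kappa = pars$kappa)
}

#' Ellipsoidal cell phantom ground truth
#'
#' Records the true geometry of a 3D cell phantom: semi-axes `a >= b >= c`
#' (um), its centre, and the implied closed-form volume `4/3 * pi * a*b*c`
#' and longitudinal extent `2a`.
#'
#' @param semi_axes Length-3 numeric, semi-axes in um, sorted decreasing.
#' @param center Length-3 numeric, phantom centre in um (default origin;
#'   the generator recentres the phantom inside its volume).
#' @return An object of class `phantom_truth` with fields `semi_axes`,
#'   `center`, `true_volume`, `true_longitudinal`, `true_transverse`.
#' @export
phantom_truth <- function(semi_axes, center = c(0, 0, 0)) {
  if (length(semi_axes) != 3 || any(semi_axes <= 0))
    stop("`semi_axes` must be 3 positive values", call. = FALSE)
  semi_axes <- sort(as.numeric(semi_axes), decreasing = TRUE)
  structure(
    list(semi_axes = semi_axes, center = as.numeric(center),
         true_volume = 4 / 3 * pi * prod(semi_axes),
         true_longitudinal = 2 * semi_axes[1],
         true_transverse = 2 * semi_axes[2]),
    class = "phantom_truth"
  )
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
# kappa == 0 falls back to the uniform circular distribution.
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(mu + runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(max(-1, min(1, f)))
      i <- i + 1L
    }
  }
  out
}

maybe_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  invisible(NULL)
}
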