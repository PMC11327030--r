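#' 2D fiber image container
#'
#' Wraps a 2D intensity matrix with its pixel size, as produced by an
#' SHG-like acquisition or by [generate_fiber_image()]. Rows index y,
#' columns index x.
#'
#' @param intensity Numeric matrix, at least 16 x 16.
#' @param pixel_size um per pixel (> 0).
#' @param layer Optional layer label ("top", "middle", "bottom").
#' @param segments Optional ground-truth segment table (synthetic images).
#' @return An object of class `fiber_image`.
#' @export
fiber_image <- function(intensity, pixel_size, layer = NULL, segments = NULL) {
  intensity <- as.matrix(intensity)
  if (any(dim(intensity) < 16))
    stop("fiber images must be at least 16x16 pixels", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  structure(
    list(intensity = intensity, pixel_size = pixel_size, layer = layer,
         segments = segments),
    class = "fiber_image"
  )
}

#' @export
print.fiber_image <- function(x, ...) {
  cat(sprintf("<fiber_image> %d x %d px @ %g um/px%s\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              if (is.null(x$layer)) "" else paste0(" [", x$layer, "]")))
  invisible(x)
}

# additive anti-aliased rendering of one segment into `img` (modified copy
# returned); coverage ramps linearly over the last pixel of the half-width,
# so overlapping fibers accumulate intensity like coaligned SHG scatterers.
render_segment <- function(img, x1, y1, x2, y2, half_w, level) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- ceiling(half_w + 1)
  c0 <- max(1L, floor(min(x1, x2)) - pad); c1 <- min(nc, ceiling(max(x1, x2)) + pad)
  r0 <- max(1L, floor(min(y1, y2)) - pad); r1 <- min(nr, ceiling(max(y1, y2)) + pad)
  if (c0 > c1 || r0 > r1) return(img)
  xs <- c0:c1; ys <- r0:r1
  px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  if (len2 == 0) {
    d <- sqrt((px - x1)^2 + (py - y1)^2)
  } else {
    t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / len2))
    d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
  }
  cov <- pmin(1, pmax(0, half_w + 0.5 - d))
  img[ys, xs] <- img[ys, xs] + level * cov
  img
}

#' Generate a synthetic SHG-like fiber image
#'
#' Renders `n_fibers` straight, anti-aliased fiber segments with centres
#' uniform over the field, Gaussian lengths (resampled to stay positive),
#' von Mises-distributed axis orientations and the given width. Intensity
#' is additive where fibers overlap, clipped at `spec$saturation`, then
#' Gaussian noise is added. The rendered ground-truth segment list is
#' returned with the image so downstream estimators can be validated.
#'
#' @param spec A [fiber_field_spec()].
#' @param config A [sim_config()] supplying `pixel_size` and `seed`.
#' @return A [fiber_image()] whose `segments` field is a data frame with
#'   the pixel endpoints, angle (radians) and true length (um) per fiber.
#' @examples
#' img <- generate_fiber_image(fiber_field_spec(n_fibers = 30), sim_config(seed = 2))
#' @export
generate_fiber_image <- function(spec, config) {
  stopifnot(inherits(spec, "fiber_field_spec"), inherits(config, "sim_config"))
  maybe_seed(config)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  px <- config$pixel_size
  img <- matrix(0, nr, nc)
  segs <- NULL
  if (spec$n_fibers > 0) {
    cx <- runif(spec$n_fibers, 0.5, nc + 0.5)
    cy <- runif(spec$n_fibers, 0.5, nr + 0.5)
    # axial orientation: half the angle of a von Mises draw gives a
    # distribution over [0, pi) whose concentration is set by kappa
    theta <- rvonmises(spec$n_fibers, 0, spec$orientation_kappa) / 2
    len_um <- rnorm(spec$n_fibers, spec$mean_length, spec$length_sd)
    bad <- len_um <= 0
    while (any(bad)) {
      len_um[bad] <- rnorm(sum(bad), spec$mean_length, spec$length_sd)
      bad <- len_um <= 0
    }
    half_px <- len_um / px / 2
    half_w <- spec$width / px / 2
    x1 <- cx - half_px * cos(theta); x2 <- cx + half_px * cos(theta)
    y1 <- cy - half_px * sin(theta); y2 <- cy + half_px * sin(theta)
    for (i in seq_len(spec$n_fibers))
      img <- render_segment(img, x1[i], y1[i], x2[i], y2[i], half_w,
                            spec$fiber_level)
    segs <- data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                       angle = theta, length_um = len_um)
  }
  img <- pmin(img + spec$background_level, spec$saturation)
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
  fiber_image(img, pixel_size = px, segments = segs)
}
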