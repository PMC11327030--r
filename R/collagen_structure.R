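#' Binarize a fiber image
#'
#' Converts an intensity image to a black-and-white fiber mask. `"otsu"`
#' picks the threshold maximising between-class variance over a 256-bin
#' histogram; `"fixed"` applies a user threshold, which should be kept
#' identical across all images of a batch so that conditions remain
#' comparable (the consistency rule used for real SHG stacks). Pixels at or
#' above the threshold are fiber.
#'
#' @param image A [fiber_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold for `method = "fixed"`.
#' @return An object of class `binary_fiber_mask` with fields `mask`
#'   (logical matrix), `pixel_size` and `threshold_used`.
#' @export
binarize_fibers <- function(image, method = c("otsu", "fixed"),
                            fixed_threshold = NULL) {
  stopifnot(inherits(image, "fiber_image"))
  method <- match.arg(method)
  x <- image$intensity
  if (method == "fixed") {
    if (is.null(fixed_threshold))
      stop("method = 'fixed' requires `fixed_threshold`", call. = FALSE)
    thr <- fixed_threshold
  } else {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("constant image: Otsu threshold is degenerate, mask is empty",
              call. = FALSE)
      return(structure(list(mask = matrix(FALSE, nrow(x), ncol(x)),
                            pixel_size = image$pixel_size,
                            threshold_used = NA_real_),
                       class = "binary_fiber_mask"))
    }
    thr <- otsu_threshold(x)
  }
  structure(
    list(mask = x >= thr, pixel_size = image$pixel_size, threshold_used = thr),
    class = "binary_fiber_mask"
  )
}

#' @export
print.binary_fiber_mask <- function(x, ...) {
  cat(sprintf("<binary_fiber_mask> %d x %d px @ %g um/px, %.1f%% fiber (thr %s)\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size, 100 * mean(x$mask),
              format(x$threshold_used)))
  invisible(x)
}

# Otsu's method on a 256-bin histogram; returns a threshold on the
# intensity scale (lower edge of the first foreground bin)
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[n_bins]; tot_mu <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- mu[-n_bins] / w0
  m1 <- (tot_mu - mu[-n_bins]) / w1
  between <- w0 * w1 * (m0 - m1)^2
  between[!valid] <- -Inf
  breaks[which.max(between) + 1]
}

#' Sample fiber lengths from a binary mask
#'
#' Skeletonises the mask (Zhang-Suen thinning), decomposes the skeleton
#' into branch segments at junction pixels, samples `n_samples` segments
#' without replacement (all of them if fewer exist) and returns each
#' segment's geodesic length in um. This automates the manual protocol of
#' measuring twenty randomly chosen fibers per layer with a ruler tool.
#'
#' Where fibers cross, junction removal leaves sub-pixel-scale fragments
#' that no human would select as "a fiber"; segments shorter than
#' `min_length` um (default 2) are therefore excluded before sampling.
#'
#' @param mask A `binary_fiber_mask`.
#' @param n_samples Number of segments to sample (default 20).
#' @param seed Optional integer seed for the sampling.
#' @param min_length Minimum segment length considered a fiber, um
#'   (default 2; set 0 to keep every fragment).
#' @return Numeric vector of lengths, um.
#' @export
measure_fiber_lengths <- function(mask, n_samples = 20, seed = NULL,
                                  min_length = 2) {
  stopifnot(inherits(mask, "binary_fiber_mask"))
  if (!any(mask$mask)) stop("mask contains no fiber pixels", call. = FALSE)
  skel <- skeletonize_mask(mask$mask)
  lens_px <- skeleton_segments(skel)
  lens_px <- lens_px[lens_px * mask$pixel_size >= min_length]
  if (!length(lens_px)) stop("no fiber segments found after thinning", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (length(lens_px) > n_samples)
    lens_px <- sample(lens_px, n_samples, replace = FALSE)
  lens_px * mask$pixel_size
}

# summed-area table: S[i+1, j+1] = sum of m[1..i, 1..j]
summed_area <- function(m) {
  cc <- apply(m, 2, cumsum)
  if (is.null(dim(cc))) cc <- matrix(cc, nrow = 1)
  S <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  S[-1, -1] <- t(apply(cc, 1, cumsum))
  S
}

# counts of fiber pixels in every s x s window (vectorised via SAT)
window_counts <- function(S, s) {
  nr <- nrow(S) - 1; nc <- ncol(S) - 1
  if (s > nr || s > nc) return(NULL)
  i <- 1:(nr - s + 1); j <- 1:(nc - s + 1)
  S[i + s, j + s, drop = FALSE] - S[i, j + s, drop = FALSE] -
    S[i + s, j, drop = FALSE] + S[i, j, drop = FALSE]
}

#' Free-space length Lf
#'
#' The Lf value: the side length of the largest axis-aligned square that
#' contains no fiber pixel, a proxy for the pore scale of the matrix.
#' `mode = "deterministic"` (default) finds the exact maximum by a binary
#' search over the side length with summed-area-table window counts.
#' `mode = "monte_carlo"` implements the stochastic reading of the same
#' estimand: the largest side for which the *modal* fiber-pixel count over
#' `n_draws` uniformly placed squares is zero. The modal criterion asks
#' that empty placements be the most common outcome, not merely possible,
#' so the Monte Carlo value is never larger than the deterministic one and
#' is typically smaller on sparse masks (see the methods vignette); the two
#' coincide on structured masks whose empty space dominates.
#'
#' @param mask A `binary_fiber_mask`.
#' @param mode `"deterministic"` or `"monte_carlo"`.
#' @param n_draws Number of random placements per candidate side
#'   (monte_carlo mode; default 2000).
#' @param seed Optional seed (monte_carlo mode).
#' @return Lf in um (0 for an all-fiber mask; the full image side for an
#'   empty mask).
#' @export
free_space_length <- function(mask, mode = c("deterministic", "monte_carlo"),
                              n_draws = 2000, seed = NULL) {
  stopifnot(inherits(mask, "binary_fiber_mask"))
  mode <- match.arg(mode)
  m <- mask$mask
  if (all(m)) return(0)
  if (!any(m)) return(min(dim(m)) * mask$pixel_size)
  S <- summed_area(m)
  ok <- switch(mode,
    deterministic = function(s) {
      w <- window_counts(S, s)
      !is.null(w) && any(w == 0)
    },
    monte_carlo = {
      if (!is.null(seed)) set.seed(seed)
      function(s) {
        if (s > min(dim(m))) return(FALSE)
        i <- sample.int(nrow(m) - s + 1, n_draws, replace = TRUE)
        j <- sample.int(ncol(m) - s + 1, n_draws, replace = TRUE)
        counts <- S[cbind(i + s, j + s)] - S[cbind(i, j + s)] -
          S[cbind(i + s, j)] + S[cbind(i, j)]
        tab <- table(counts)
        names(tab)[which.max(tab)] == "0"
      }
    })
  lo <- 0L; hi <- min(dim(m))
  while (lo < hi) {           # invariant: ok(lo) holds (lo = 0 trivially)
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (ok(mid)) lo <- mid else hi <- mid - 1L
  }
  lo * mask$pixel_size
}

#' Centered 2D power spectrum
#'
#' Mean-subtracted, optionally Hann-windowed 2D discrete Fourier transform;
#' returns `|F|^2` with zero frequency at the centre. The Hann window
#' (default) suppresses edge ringing; use `window = "none"` when exact
#' Parseval bookkeeping is needed.
#'
#' @param image A [fiber_image()] or a plain numeric matrix.
#' @param window `"hann"` or `"none"`.
#' @param pixel_size um/pixel, required when `image` is a bare matrix.
#' @return An object of class `power_spectrum`: fields `power` (matrix,
#'   DC-centred), `fy`, `fx` (cycles/pixel along rows and columns),
#'   `pixel_size`, `n_pixels`, `window`.
#' @export
fft_power_spectrum <- function(image, window = c("hann", "none"),
                               pixel_size = NULL) {
  window <- match.arg(window)
  if (inherits(image, "fiber_image")) {
    x <- image$intensity
    pixel_size <- image$pixel_size
  } else {
    x <- as.matrix(image)
    if (is.null(pixel_size)) pixel_size <- 1
  }
  nr <- nrow(x); nc <- ncol(x)
  x <- x - mean(x)
  if (window == "hann") {
    wr <- 0.5 * (1 - cos(2 * pi * (0:(nr - 1)) / (nr - 1)))
    wc <- 0.5 * (1 - cos(2 * pi * (0:(nc - 1)) / (nc - 1)))
    x <- x * outer(wr, wc)
  }
  P <- Mod(stats::fft(x))^2
  shift_idx <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))
  P <- P[shift_idx(nr), shift_idx(nc)]
  freq <- function(n) {
    f <- (0:(n - 1)) / n
    f[f >= 0.5] <- f[f >= 0.5] - 1
    sort(f)
  }
  structure(
    list(power = P, fy = freq(nr), fx = freq(nc), pixel_size = pixel_size,
         n_pixels = nr * nc, window = window),
    class = "power_spectrum"
  )
}

#' Spectral anisotropy ellipse
#'
#' Thresholds the power spectrum at a high power quantile and computes the
#' second moments of the retained power in frequency space. Aligned fibers
#' concentrate spectral power along the direction perpendicular to the
#' fiber axis, so the real-space dominant fiber orientation is reported
#' perpendicular to the spectral major axis. The anisotropy ratio (major
#' over minor ellipse axis, >= 1) is near 1 for isotropic fiber fields and
#' grows with alignment.
#'
#' @param spectrum A `power_spectrum`.
#' @param power_quantile Quantile above which spectral pixels are retained
#'   (default 0.95).
#' @return A list with `anisotropy_ratio` (>= 1), `dominant_orientation`
#'   (degrees in (-90, 90], 0 = horizontal fibers) and `n_retained`. Both
#'   statistics are `NA` when fewer than 5 pixels survive the threshold.
#' @export
anisotropy_ellipse <- function(spectrum, power_quantile = 0.95) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  P <- spectrum$power
  thr <- quantile(P, power_quantile)
  keep <- which(P >= thr & P > 0, arr.ind = TRUE)
  if (nrow(keep) < 5)
    return(list(anisotropy_ratio = NA_real_, dominant_orientation = NA_real_,
                n_retained = nrow(keep)))
  w <- P[keep]
  fy <- spectrum$fy[keep[, 1]]
  fx <- spectrum$fx[keep[, 2]]
  W <- sum(w)
  cxx <- sum(w * fx^2) / W; cyy <- sum(w * fy^2) / W; cxy <- sum(w * fx * fy) / W
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  ratio <- sqrt(max(e$values[1], 0) / max(e$values[2], .Machine$double.eps))
  major <- e$vectors[, 1]
  spectral_angle <- atan2(major[2], major[1]) * 180 / pi
  fiber_angle <- spectral_angle + 90
  fiber_angle <- ((fiber_angle + 90) %% 180) - 90
  list(anisotropy_ratio = ratio, dominant_orientation = fiber_angle,
       n_retained = nrow(keep))
}

#' Pore and fiber size from the radial power profile
#'
#' Radially averages the power spectrum, locates the dominant non-zero
#' spatial frequency `f*`, and converts it to a characteristic spacing
#' `1/f*` (um). The spacing is then split into the width occupied by fiber
#' and by pore using the fiber area fraction of the matching binary mask:
#' `fiber_size = spacing * fraction`, `pore_size = spacing - fiber_size`.
#' The first two rings around DC are excluded (window leakage); if no ring
#' stands out above the profile background (maximum < 2x the median, as in
#' a pure-noise image) the result is flagged undefined.
#'
#' @param spectrum A `power_spectrum`.
#' @param fiber_fraction Fiber area fraction of the matching mask, in
#'   \[0, 1\] (e.g. `mean(mask$mask)` or [shg_positive_fraction()] / 100).
#' @param pixel_size um/pixel; defaults to the spectrum's.
#' @return A list with `spacing`, `pore_size`, `fiber_size` (um), `f_star`
#'   (cycles/pixel), `undefined` flag, and the ring `profile` data frame.
#' @export
radial_size_profile <- function(spectrum, fiber_fraction, pixel_size = NULL) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (is.null(pixel_size)) pixel_size <- spectrum$pixel_size
  if (fiber_fraction < 0 || fiber_fraction > 1)
    stop("`fiber_fraction` must be in [0, 1]", call. = FALSE)
  P <- spectrum$power
  n_ref <- min(dim(P))
  rad <- sqrt(outer(spectrum$fy^2, spectrum$fx^2, "+"))
  ring <- round(rad * n_ref)
  max_ring <- floor(n_ref / 2)
  sel <- ring >= 2 & ring <= max_ring
  prof <- tapply(P[sel], ring[sel], mean)
  rings <- as.integer(names(prof))
  profile <- data.frame(ring = rings, f = rings / n_ref, power = as.numeric(prof))
  peak <- which.max(profile$power)
  undefined <- profile$power[peak] < 2 * median(profile$power)
  if (undefined)
    return(list(spacing = NA_real_, pore_size = NA_real_,
                fiber_size = NA_real_, f_star = NA_real_, undefined = TRUE,
                profile = profile))
  f_star <- profile$f[peak]
  spacing <- pixel_size / f_star
  fiber_size <- spacing * fiber_fraction
  list(spacing = spacing, pore_size = spacing - fiber_size,
       fiber_size = fiber_size, f_star = f_star, undefined = FALSE,
       profile = profile)
}

#' Percentage of SHG-positive pixels
#'
#' Fraction of pixels at or above the threshold, as a percentage; the
#' standard measure of how much of a region is occupied by collagen signal.
#'
#' @param image A [fiber_image()] or numeric matrix.
#' @param threshold Intensity threshold.
#' @return Percentage in \[0, 100\].
#' @export
shg_positive_fraction <- function(image, threshold) {
  x <- if (inherits(image, "fiber_image")) image$intensity else as.matrix(image)
  100 * mean(x >= threshold)
}

#' Structure metrics for one fiber image
#'
#' Convenience wrapper running the full structural analysis of a single
#' SHG-like layer: binarisation, sampled fiber lengths, free-space length
#' Lf, spectral anisotropy, pore/fiber size and the SHG-positive fraction.
#'
#' @param image A [fiber_image()].
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold when `threshold_method = "fixed"`.
#' @param n_fiber_samples Number of fiber segments to sample (default 20).
#' @param lf_mode Lf estimation mode (see [free_space_length()]).
#' @param power_quantile Quantile for [anisotropy_ellipse()].
#' @param seed Optional seed for fiber sampling.
#' @return A list of class `structure_metrics` with fields
#'   `fiber_lengths`, `fiber_length_mean`, `lf`, `anisotropy_ratio`,
#'   `dominant_orientation`, `pore_size`, `fiber_size`,
#'   `shg_positive_fraction`, `threshold_used`.
#' @export
structure_metrics <- function(image, threshold_method = c("otsu", "fixed"),
                              fixed_threshold = NULL, n_fiber_samples = 20,
                              lf_mode = "deterministic",
                              power_quantile = 0.95, seed = NULL) {
  stopifnot(inherits(image, "fiber_image"))
  mask <- binarize_fibers(image, method = threshold_method,
                          fixed_threshold = fixed_threshold)
  lengths <- if (any(mask$mask))
    measure_fiber_lengths(mask, n_samples = n_fiber_samples, seed = seed)
  else numeric(0)
  spec <- fft_power_spectrum(image)
  aniso <- anisotropy_ellipse(spec, power_quantile)
  sizes <- radial_size_profile(spec, fiber_fraction = mean(mask$mask))
  structure(
    list(fiber_lengths = lengths,
         fiber_length_mean = if (length(lengths)) mean(lengths) else NA_real_,
         lf = free_space_length(mask),
         anisotropy_ratio = aniso$anisotropy_ratio,
         dominant_orientation = aniso$dominant_orientation,
         pore_size = sizes$pore_size, fiber_size = sizes$fiber_size,
         shg_positive_fraction = 100 * mean(mask$mask),
         threshold_used = mask$threshold_used),
    class = "structure_metrics"
  )
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat("<structure_metrics>\n")
  cat(sprintf("  fiber length : %.1f um (n = %d sampled)\n",
              x$fiber_length_mean, length(x$fiber_lengths)))
  cat(sprintf("  Lf           : %.1f um\n", x$lf))
  cat(sprintf("  anisotropy   : %.2f @ %.0f deg\n", x$anisotropy_ratio,
              x$dominant_orientation))
  cat(sprintf("  pore / fiber : %.1f / %.1f um\n", x$pore_size, x$fiber_size))
  cat(sprintf("  SHG-positive : %.1f %%\n", x$shg_positive_fraction))
  invisible(x)
}
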