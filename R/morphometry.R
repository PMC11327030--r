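#' Two-channel 3D cell image
#'
#' Aligned membrane-analogue (F-actin) and nucleus-analogue intensity
#' volumes with their voxel size. Arrays are indexed (x, y, z).
#'
#' @param membrane,nucleus 3D numeric arrays of identical dimensions.
#' @param voxel_size um per axis, length 3 (> 0).
#' @param truth Optional [phantom_truth()] record (synthetic volumes).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(membrane, nucleus, voxel_size, truth = NULL) {
  if (!identical(dim(membrane), dim(nucleus)))
    stop("the two channels must share dimensions", call. = FALSE)
  if (length(dim(membrane)) != 3)
    stop("channels must be 3D arrays", call. = FALSE)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive values", call. = FALSE)
  structure(
    list(membrane = membrane, nucleus = nucleus,
         voxel_size = as.numeric(voxel_size), truth = truth),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels @ %s um\n",
              paste(dim(x$membrane), collapse = " x "),
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Segmented 3D cell mask
#'
#' @param mask 3D logical array (TRUE = cell voxel).
#' @param voxel_size um per axis, length 3.
#' @return An object of class `cell_mask_3d`.
#' @export
cell_mask_3d <- function(mask, voxel_size) {
  if (length(dim(mask)) != 3) stop("`mask` must be a 3D array", call. = FALSE)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  structure(list(mask = mask, voxel_size = as.numeric(voxel_size)),
            class = "cell_mask_3d")
}

#' Hierarchical k-means intensity segmentation
#'
#' Clusters voxel intensities into `n_classes` by hierarchical 1D k-means
#' over a 256-bin histogram: starting from a single class, the class with
#' the largest within-class sum of squares is repeatedly split at the
#' boundary minimising the residual sum of squares, until `n_classes`
#' contiguous intensity intervals exist. The brightest class is taken as
#' foreground, and connected components smaller than `min_region_voxels`
#' are removed. Deterministic (no random initialisation).
#'
#' The defaults (3 classes, 10,000-voxel minimum region) match the settings
#' used for confocal cell stacks at full acquisition resolution; scale
#' `min_region_voxels` down for small test volumes.
#'
#' @param channel 3D numeric array (one intensity channel).
#' @param n_classes Number of intensity classes (default 3).
#' @param min_region_voxels Minimum connected-component size kept in the
#'   foreground (default 10000).
#' @param n_bins Histogram bins (default 256).
#' @return 3D logical array (foreground mask).
#' @export
hkmeans_segment <- function(channel, n_classes = 3, min_region_voxels = 10000,
                            n_bins = 256) {
  if (length(dim(channel)) != 3)
    stop("`channel` must be a 3D array", call. = FALSE)
  rng <- range(channel)
  if (diff(rng) == 0)
    stop("constant intensities: nothing to segment", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(channel, breaks, rightmost.closed = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # prefix sums for O(1) interval statistics on the histogram
  W <- cumsum(h); WV <- cumsum(h * mids); WV2 <- cumsum(h * mids^2)
  iv_stats <- function(lo, hi) {
    w <- W[hi] - if (lo > 1) W[lo - 1] else 0
    s <- WV[hi] - if (lo > 1) WV[lo - 1] else 0
    s2 <- WV2[hi] - if (lo > 1) WV2[lo - 1] else 0
    list(w = w, mean = if (w > 0) s / w else NA_real_,
         ss = if (w > 0) s2 - s^2 / w else 0)
  }
  intervals <- list(c(1L, n_bins))
  while (length(intervals) < n_classes) {
    ss <- vapply(intervals, function(iv) iv_stats(iv[1], iv[2])$ss, numeric(1))
    k <- which.max(ss)
    iv <- intervals[[k]]
    if (iv[1] >= iv[2] || ss[k] == 0) break  # nothing left to split
    cuts <- iv[1]:(iv[2] - 1L)
    resid <- vapply(cuts, function(cut)
      iv_stats(iv[1], cut)$ss + iv_stats(cut + 1L, iv[2])$ss, numeric(1))
    cut <- cuts[which.min(resid)]
    intervals[[k]] <- c(iv[1], cut)
    intervals[[length(intervals) + 1L]] <- c(cut + 1L, iv[2])
  }
  means <- vapply(intervals, function(iv) iv_stats(iv[1], iv[2])$mean, numeric(1))
  top <- intervals[[which.max(means)]]
  fg_threshold <- breaks[top[1]]
  mask <- array(channel >= fg_threshold, dim(channel))
  prune_small_components(mask, min_region_voxels)
}

#' Fill holes per channel and take the union
#'
#' Fills interior cavities of each channel mask independently (background
#' voxels with no 6-connected path to the border), takes the voxelwise
#' union, and keeps the largest connected component. With a membrane shell
#' and a nuclear core this yields a solid, single-component cell mask. The
#' operation is idempotent.
#'
#' @param mask_a,mask_b 3D logical arrays of identical dimensions (or a
#'   `cell_mask_3d` for `mask_a` with `mask_b` missing, for idempotent
#'   reapplication).
#' @param voxel_size um per axis, length 3.
#' @return A [cell_mask_3d()].
#' @export
fill_and_union <- function(mask_a, mask_b = NULL, voxel_size = c(1, 1, 1)) {
  if (inherits(mask_a, "cell_mask_3d")) {
    voxel_size <- mask_a$voxel_size
    mask_a <- mask_a$mask
  }
  if (is.null(mask_b)) mask_b <- mask_a
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must share dimensions", call. = FALSE)
  u <- fill_holes_3d(mask_a) | fill_holes_3d(mask_b)
  if (!any(u)) stop("empty segmentation: union of masks has no voxels",
                    call. = FALSE)
  cell_mask_3d(largest_component(u), voxel_size)
}

#' Cell volume from a 3D mask
#'
#' Number of foreground voxels times the voxel volume.
#'
#' @param mask A [cell_mask_3d()].
#' @return Volume in um^3.
#' @export
cell_volume <- function(mask) {
  stopifnot(inherits(mask, "cell_mask_3d"))
  n <- sum(mask$mask)
  if (n == 0) stop("empty mask has no volume", call. = FALSE)
  n * prod(mask$voxel_size)
}

#' Longitudinal and transverse axis lengths
#'
#' The longitudinal axis is the 3D Feret diameter: the maximum Euclidean
#' distance between surface voxels (the distance "between the furthest
#' points"). The transverse axis is the maximum extent measured
#' perpendicular to the longitudinal direction (the diameter of the mask's
#' projection onto the orthogonal plane). Candidate extreme voxels are
#' found as support points over a dense set of directions, then measured
#' exactly pairwise; anisotropic voxels are scaled to um first, so both
#' statistics are rotation invariant up to discretisation.
#'
#' @param mask A [cell_mask_3d()].
#' @param n_directions Number of sphere directions used to collect extreme
#'   candidates (default 500).
#' @return A list with `longitudinal` and `transverse` (um) and a
#'   `degenerate` flag (TRUE for a single-voxel mask, where both axes are
#'   reported as the voxel diagonal).
#' @export
axis_lengths <- function(mask, n_directions = 500) {
  stopifnot(inherits(mask, "cell_mask_3d"))
  m <- mask$mask
  if (!any(m)) stop("empty mask has no axes", call. = FALSE)
  vox <- mask$voxel_size
  if (sum(m) == 1) {
    diag_len <- sqrt(sum(vox^2))
    return(list(longitudinal = diag_len, transverse = diag_len,
                degenerate = TRUE))
  }
  # surface voxels: foreground with at least one 6-connected background
  pad <- pad_3d(m)
  offs <- neighbor_offsets_3d(dim(pad), 6)
  fg <- which(pad)
  has_bg <- rep(FALSE, length(fg))
  for (o in offs) has_bg <- has_bg | !pad[fg + o]
  surf <- fg[has_bg]
  d <- dim(pad)
  idx <- arrayInd(surf, d) - 1L  # remove padding offset
  centers <- sweep(idx, 2, vox, "*")
  # Voxel centers bias the Feret diameter low (the solid extends half a
  # voxel beyond the outermost inside centre); cube corners bias it high by
  # the same margin in the opposite rotation-dependent way. The midpoint of
  # the two support estimates is unbiased to within discretisation noise.
  corner_offs <- sweep(as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5),
                                             c(-0.5, 0.5))), 2, vox, "*")
  corners <- unique(do.call(rbind, lapply(seq_len(8), function(k)
    sweep(centers, 2, corner_offs[k, ], "+"))))
  feret <- function(pts, dirs) {
    proj <- pts %*% t(dirs)
    cand_idx <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
    cand <- pts[cand_idx, , drop = FALSE]
    D <- as.matrix(dist(cand))
    ext <- which(D == max(D), arr.ind = TRUE)[1, ]
    list(len = max(D), u = cand[ext[1], ] - cand[ext[2], ])
  }
  dirs <- fibonacci_directions(n_directions)
  f_ctr <- feret(centers, dirs)
  f_cor <- feret(corners, dirs)
  longitudinal <- (f_ctr$len + f_cor$len) / 2
  u <- f_cor$u / sqrt(sum(f_cor$u^2))
  # orthonormal basis of the plane perpendicular to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- ref - sum(ref * u) * u; v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  ang <- seq(0, pi, length.out = 181)[-181]
  w <- cbind(cos(ang), sin(ang))
  plane_extent <- function(pts) {
    q <- cbind(pts %*% v1, pts %*% v2)
    pr <- q %*% t(w)
    max(apply(pr, 2, max) - apply(pr, 2, min))
  }
  transverse <- (plane_extent(centers) + plane_extent(corners)) / 2
  list(longitudinal = longitudinal, transverse = transverse,
       degenerate = FALSE)
}

#' Full morphometry of a two-channel cell volume
#'
#' Runs the standard pipeline: segment each channel with
#' [hkmeans_segment()], fill holes and take the union
#' ([fill_and_union()]), then measure volume and axis lengths.
#'
#' @param volume A [volume_image()].
#' @param n_classes Intensity classes for segmentation (default 3).
#' @param min_region_voxels Minimum region size (default 10000; scale down
#'   for small volumes).
#' @return A list with `volume` (um^3), `longitudinal`, `transverse` (um),
#'   `degenerate` flag, and the final `mask` (a [cell_mask_3d()]).
#' @examples
#' ph <- generate_cell_phantom(phantom_truth(c(10, 5, 5)), sim_config(seed = 4))
#' mm <- morpho_metrics(ph, min_region_voxels = 100)
#' @export
morpho_metrics <- function(volume, n_classes = 3, min_region_voxels = 10000) {
  stopifnot(inherits(volume, "volume_image"))
  ma <- hkmeans_segment(volume$membrane, n_classes, min_region_voxels)
  mb <- hkmeans_segment(volume$nucleus, n_classes, min_region_voxels)
  mask <- fill_and_union(ma, mb, voxel_size = volume$voxel_size)
  ax <- axis_lengths(mask)
  list(volume = cell_volume(mask), longitudinal = ax$longitudinal,
       transverse = ax$transverse, degenerate = ax$degenerate, mask = mask)
}
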