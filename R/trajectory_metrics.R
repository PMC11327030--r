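#' Analysis parameters for trajectory metrics
#'
#' @param cell_diameter Nominal cell diameter, um (default 50, the blob
#'   diameter used when tracking these cells).
#' @param static_threshold Path-length threshold below which a cell is
#'   classified static, um. Default `1.5 * cell_diameter` = 75 um.
#' @param min_track_frames Minimum number of positions for the alpha fit;
#'   shorter tracks get `alpha = NA` but still contribute to speed,
#'   persistence and the static count (default 10).
#' @param max_lag_fraction Fraction of the track length used as the largest
#'   MSD lag (default 0.25; must be in (0, 0.5] -- short-lag fits are
#'   standard practice for single-particle tracks).
#' @param max_lag Optional explicit largest lag in frames; overrides
#'   `max_lag_fraction` when given.
#' @param min_pairs Minimum number of displacement pairs a lag must average
#'   over to be retained in the MSD curve (default 3).
#' @return An object of class `analysis_params`.
#' @export
analysis_params <- function(cell_diameter = 50,
                            static_threshold = 1.5 * cell_diameter,
                            min_track_frames = 10,
                            max_lag_fraction = 0.25,
                            max_lag = NULL,
                            min_pairs = 3) {
  if (static_threshold <= 0) stop("`static_threshold` must be > 0", call. = FALSE)
  if (is.null(max_lag) &&
      (max_lag_fraction <= 0 || max_lag_fraction > 0.5))
    stop("`max_lag_fraction` must be in (0, 0.5]", call. = FALSE)
  if (min_pairs < 1) stop("`min_pairs` must be >= 1", call. = FALSE)
  structure(
    list(cell_diameter = cell_diameter, static_threshold = static_threshold,
         min_track_frames = as.integer(min_track_frames),
         max_lag_fraction = max_lag_fraction,
         max_lag = if (is.null(max_lag)) NULL else as.integer(max_lag),
         min_pairs = as.integer(min_pairs)),
    class = "analysis_params"
  )
}

#' Mean instantaneous speed
#'
#' Mean over consecutive observed frame pairs of step length divided by the
#' elapsed time. Steps that span frame gaps use the true elapsed time, so a
#' gap does not inflate the speed.
#'
#' @param traj A [trajectory()].
#' @return Speed in um/min.
#' @examples
#' mean_speed(trajectory(cbind(c(0, 0), c(0, 4)), frame_interval = 10))  # 0.4
#' @export
mean_speed <- function(traj) {
  s <- traj_steps(traj)
  mean(s$lengths / s$dt_min)
}

#' Directional persistence ratio
#'
#' Net displacement divided by total path length; 1 for perfectly straight
#' motion, 0 for a closed loop. A zero-length path is defined to have
#' persistence 0 (the cell went nowhere, so no direction was maintained).
#'
#' @param traj A [trajectory()].
#' @return A fraction in \[0, 1\].
#' @export
persistence <- function(traj) {
  total <- path_length(traj)
  if (total == 0) return(0)
  net_displacement(traj) / total
}

#' Classify a track as static
#'
#' A cell is static when its total path length over the acquisition is
#' strictly smaller than the threshold (default 75 um = 1.5 cell
#' diameters); such cells are typically stuck in the matrix. Ties at the
#' threshold count as motile.
#'
#' @param traj A [trajectory()].
#' @param params An [analysis_params()].
#' @return Logical.
#' @export
classify_static <- function(traj, params = analysis_params()) {
  path_length(traj) < params$static_threshold
}

#' Time-averaged mean-squared displacement curve
#'
#' For each lag `l` (frames) up to `floor(max_lag_fraction * n)` (or
#' `params$max_lag`), averages `|r(t + l) - r(t)|^2` over every pair of
#' observed frames exactly `l` apart. Pairs that straddle a tracking gap
#' simply do not exist at that lag and are excluded. Lags averaging fewer
#' than `params$min_pairs` pairs are dropped.
#'
#' @param traj A [trajectory()] with at least 3 positions (shorter tracks
#'   return an undefined-result curve rather than an error).
#' @param params An [analysis_params()].
#' @return An object of class `msd_curve`: a data frame with columns
#'   `lag_frames`, `lag_min`, `msd` (um^2) and `n_pairs`, plus an
#'   `undefined` attribute.
#' @examples
#' tr <- trajectory(cbind(c(0, 1, 2), c(0, 0, 0)), frame_interval = 10)
#' msd_curve(tr, analysis_params(max_lag = 2, min_pairs = 1))
#' @export
msd_curve <- function(traj, params = analysis_params()) {
  n <- nrow(traj$positions)
  if (n < 3) {
    out <- data.frame(lag_frames = integer(0), lag_min = numeric(0),
                      msd = numeric(0), n_pairs = integer(0))
    class(out) <- c("msd_curve", "data.frame")
    attr(out, "undefined") <- TRUE
    return(out)
  }
  max_lag <- if (!is.null(params$max_lag)) params$max_lag
             else floor(params$max_lag_fraction * n)
  max_lag <- max(1L, min(max_lag, max(traj$frames) - min(traj$frames)))
  frames <- traj$frames
  pos <- traj$positions
  idx <- seq_len(n)
  lookup <- integer(max(frames) - min(frames) + 1L)
  lookup[frames - min(frames) + 1L] <- idx
  res <- lapply(seq_len(max_lag), function(l) {
    tgt_frame <- frames + l
    ok <- tgt_frame <= max(frames)
    j <- integer(length(frames)); j[] <- 0L
    j[ok] <- lookup[tgt_frame[ok] - min(frames) + 1L]
    has <- j > 0L
    if (!any(has)) return(c(NA_real_, 0))
    d2 <- rowSums((pos[j[has], , drop = FALSE] - pos[has, , drop = FALSE])^2)
    c(mean(d2), length(d2))
  })
  res <- do.call(rbind, res)
  keep <- res[, 2] >= params$min_pairs
  out <- data.frame(lag_frames = which(keep),
                    lag_min = which(keep) * traj$frame_interval,
                    msd = res[keep, 1], n_pairs = as.integer(res[keep, 2]))
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "undefined") <- nrow(out) == 0
  out
}

#' Anomalous-diffusion exponent (alpha value)
#'
#' Ordinary least-squares slope of `log(MSD)` against `log(lag)`.
#' `alpha = 1` is Brownian motion; smaller values indicate subdiffusive,
#' confined motion, larger values exploratory superdiffusion (ballistic
#' motion gives exactly 2). Zero or negative MSD values are dropped before
#' fitting; if fewer than 3 points remain the result is `NA`.
#'
#' @param msd An [msd_curve()].
#' @return The fitted exponent, or `NA_real_` when undefined.
#' @export
alpha_exponent <- function(msd) {
  if (isTRUE(attr(msd, "undefined"))) return(NA_real_)
  keep <- is.finite(msd$msd) & msd$msd > 0
  if (sum(keep) < 3) return(NA_real_)
  x <- log(msd$lag_frames[keep])
  y <- log(msd$msd[keep])
  unname(coef(lm(y ~ x))[2])
}

#' Per-track migration metrics
#'
#' Computes the four migration measures for one cell: mean instantaneous
#' speed, static classification, the MSD log-log slope (alpha) and the
#' persistence ratio, together with path length and net displacement.
#' Tracks shorter than `params$min_track_frames` get `alpha = NA` but still
#' contribute the other measures. Undefined results propagate as `NA`
#' without aborting a batch.
#'
#' @param traj A [trajectory()].
#' @param params An [analysis_params()].
#' @return A one-row data frame with columns `track_id`, `n_frames`,
#'   `mean_speed`, `path_length`, `net_displacement`, `persistence`,
#'   `alpha`, `is_static`.
#' @export
compute_track_metrics <- function(traj, params = analysis_params()) {
  alpha <- if (nrow(traj$positions) < params$min_track_frames) NA_real_
           else alpha_exponent(msd_curve(traj, params))
  data.frame(
    track_id = traj$track_id,
    n_frames = nrow(traj$positions),
    mean_speed = mean_speed(traj),
    path_length = path_length(traj),
    net_displacement = net_displacement(traj),
    persistence = persistence(traj),
    alpha = alpha,
    is_static = classify_static(traj, params),
    stringsAsFactors = FALSE
  )
}

#' Cohort summary of migration metrics
#'
#' Aggregates per-track metrics for one experimental condition into the four
#' cohort statistics: percentage of static cells, mean instantaneous speed,
#' mean alpha (over tracks with a defined fit) and percentage of persistence
#' (mean persistence x 100).
#'
#' @param metrics A data frame of rows from [compute_track_metrics()] (e.g.
#'   `do.call(rbind, lapply(trajs, compute_track_metrics))`).
#' @param condition_label Label for the condition (e.g. "1 mg/mL").
#' @param include_static Include static cells in the speed/alpha/persistence
#'   averages (default TRUE; the counting of static cells is unaffected).
#' @return A one-row data frame with columns `condition`, `n_tracks`,
#'   `percent_static`, `mean_instant_speed`, `mean_alpha`,
#'   `percent_persistence`.
#' @export
summarize_cohort <- function(metrics, condition_label = "condition",
                             include_static = TRUE) {
  if (!is.data.frame(metrics) || nrow(metrics) < 1)
    stop("`metrics` must contain at least one track", call. = FALSE)
  sub <- if (include_static) metrics else metrics[!metrics$is_static, , drop = FALSE]
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  data.frame(
    condition = condition_label,
    n_tracks = nrow(metrics),
    percent_static = 100 * mean(metrics$is_static),
    mean_instant_speed = mean_or_na(sub$mean_speed),
    mean_alpha = mean_or_na(sub$alpha),
    percent_persistence = 100 * mean_or_na(sub$persistence),
    stringsAsFactors = FALSE
  )
}
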