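#' Single-cell trajectory
#'
#' A time-ordered sequence of 2D or 3D positions (um) for one tracked cell,
#' sampled at a fixed frame interval. Frames need not be contiguous: gaps
#' left by the upstream tracker are preserved and handled explicitly by the
#' metric functions (elapsed time for speed, pair exclusion for the MSD).
#'
#' @param positions Numeric matrix (or data frame) with one row per
#'   observation and 2 or 3 columns (x, y\[, z\]) in um. At least 2 rows.
#' @param frame_interval Time between consecutive frame indices, minutes.
#' @param frames Integer frame indices, strictly increasing; default
#'   `0:(n-1)`.
#' @param track_id Identifier carried into metric tables.
#'
#' @return An object of class `trajectory`.
#' @examples
#' tr <- trajectory(cbind(x = c(0, 3, 3), y = c(0, 0, 4)), frame_interval = 10)
#' persistence(tr)  # 5/7
#' @export
trajectory <- function(positions, frame_interval = 10, frames = NULL,
                       track_id = "track") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (nrow(positions) < 2)
    stop("a trajectory needs at least 2 positions", call. = FALSE)
  if (!ncol(positions) %in% c(2L, 3L))
    stop("positions must have 2 or 3 coordinate columns", call. = FALSE)
  if (anyNA(positions) || any(!is.finite(positions)))
    stop("positions must be finite", call. = FALSE)
  if (frame_interval <= 0) stop("`frame_interval` must be > 0", call. = FALSE)
  if (is.null(frames)) frames <- seq_len(nrow(positions)) - 1L
  frames <- as.integer(frames)
  if (length(frames) != nrow(positions) || any(diff(frames) <= 0))
    stop("`frames` must be strictly increasing, one per position", call. = FALSE)
  colnames(positions) <- c("x", "y", "z")[seq_len(ncol(positions))]
  structure(
    list(track_id = track_id, frame_interval = frame_interval,
         positions = positions, frames = frames),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d positions (%dD), frames %d..%d, dt = %g min\n",
              x$track_id, nrow(x$positions), ncol(x$positions),
              x$frames[1], x$frames[length(x$frames)], x$frame_interval))
  invisible(x)
}

# step vectors between consecutive observations, with elapsed minutes
traj_steps <- function(traj) {
  d <- diff(traj$positions)
  list(lengths = sqrt(rowSums(d^2)),
       dt_min = diff(traj$frames) * traj$frame_interval)
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean step lengths between consecutive observations, um.
#' @param traj A [trajectory()].
#' @return Path length in um.
#' @export
path_length <- function(traj) sum(traj_steps(traj)$lengths)

#' Net displacement of a trajectory
#'
#' Euclidean distance between the last and first observed position, um.
#' @param traj A [trajectory()].
#' @return Net displacement in um.
#' @export
net_displacement <- function(traj) {
  p <- traj$positions
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}
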