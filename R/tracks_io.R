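#' Read tracks exported by a particle tracker
#'
#' Supports two dialects:
#' * `"csv"` -- columns `track_id`, `frame`, `x_um`, `y_um` and optionally
#'   `z_um` (a `t_min` column, if present, is ignored; time is derived from
#'   `frame * frame_interval`). This is the same schema [write_tracks()]
#'   produces.
#' * `"trackmate_xml"` -- either a full TrackMate session file
#'   (`<TrackMate>` root: spots from `AllSpots`, track membership from
#'   `AllTracks` edges) or the simplified `<Tracks>` export
#'   (`<particle><detection t x y z/></particle>`). Positions are taken in
#'   the file's physical units (um); detector/linker settings present in
#'   the file are kept as a `settings` attribute, not re-executed.
#'
#' Tracks with fewer than 2 points are rejected with a warning. Frame gaps
#' are preserved in the `frames` slot of each trajectory.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"trackmate_xml"`.
#' @param frame_interval Minutes per frame for the resulting trajectories
#'   (default 10); the TrackMate `frameInterval` attribute, when present,
#'   takes precedence.
#' @return A list of [trajectory()] objects.
#' @export
read_tracks <- function(path, dialect = c("csv", "trackmate_xml"),
                        frame_interval = 10) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(dialect,
         csv = read_tracks_csv(path, frame_interval),
         trackmate_xml = read_tracks_trackmate(path, frame_interval))
}

read_tracks_csv <- function(path, frame_interval) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "x_um", "y_um")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("track CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  coord_cols <- intersect(c("x_um", "y_um", "z_um"), names(df))
  for (col in c("frame", coord_cols)) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]),
           call. = FALSE)
    if (anyNA(vals))
      stop(sprintf("missing value in column '%s' at row %d", col,
                   which(is.na(vals))[1]), call. = FALSE)
    df[[col]] <- vals
  }
  build_track_list(split(df, df$track_id), coord_cols, frame_interval)
}

build_track_list <- function(pieces, coord_cols, frame_interval) {
  out <- list()
  dropped <- character(0)
  for (id in names(pieces)) {
    piece <- pieces[[id]]
    piece <- piece[order(piece$frame), , drop = FALSE]
    if (nrow(piece) < 2) {
      dropped <- c(dropped, id)
      next
    }
    out[[id]] <- trajectory(as.matrix(piece[coord_cols]),
                            frame_interval = frame_interval,
                            frames = piece$frame, track_id = id)
  }
  if (length(dropped))
    warning("rejected single-point track(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  unname(out)
}

read_tracks_trackmate <- function(path, frame_interval) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  if (root == "Tracks") {
    fi <- xml2::xml_attr(doc, "frameInterval")
    if (!is.na(fi)) frame_interval <- as.numeric(fi)
    particles <- xml2::xml_find_all(doc, ".//particle")
    out <- list()
    dropped <- 0L
    for (i in seq_along(particles)) {
      det <- xml2::xml_find_all(particles[[i]], ".//detection")
      if (length(det) < 2) { dropped <- dropped + 1L; next }
      num <- function(a) as.numeric(xml2::xml_attr(det, a))
      frames <- as.integer(num("t"))
      pos <- cbind(x = num("x"), y = num("y"), z = num("z"))
      if (all(is.na(pos[, "z"])) || all(pos[, "z"] == 0))
        pos <- pos[, 1:2, drop = FALSE]
      ord <- order(frames)
      out[[length(out) + 1L]] <- trajectory(pos[ord, , drop = FALSE],
                                            frame_interval = frame_interval,
                                            frames = frames[ord],
                                            track_id = sprintf("track_%d", i))
    }
    if (dropped > 0)
      warning(dropped, " track(s) with <2 detections rejected", call. = FALSE)
    return(out)
  }
  if (root != "TrackMate")
    stop("unrecognised XML root <", root, ">: expected <TrackMate> or <Tracks>",
         call. = FALSE)
  spots <- xml2::xml_find_all(doc, ".//Model/AllSpots//Spot")
  if (!length(spots)) stop("no spots found in TrackMate file", call. = FALSE)
  sp_attr <- function(a) as.numeric(xml2::xml_attr(spots, a))
  spot_tab <- data.frame(
    id = xml2::xml_attr(spots, "ID"),
    frame = as.integer(sp_attr("FRAME")),
    x_um = sp_attr("POSITION_X"), y_um = sp_attr("POSITION_Y"),
    z_um = sp_attr("POSITION_Z"), stringsAsFactors = FALSE)
  bad <- which(is.na(spot_tab$x_um) | is.na(spot_tab$y_um))
  if (length(bad))
    stop("spot ", spot_tab$id[bad[1]], " has non-numeric coordinates",
         call. = FALSE)
  tracks <- xml2::xml_find_all(doc, ".//Model/AllTracks/Track")
  pieces <- list()
  for (tr in tracks) {
    tid <- xml2::xml_attr(tr, "TRACK_ID")
    edges <- xml2::xml_find_all(tr, ".//Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    piece <- spot_tab[spot_tab$id %in% ids, , drop = FALSE]
    pieces[[paste0("track_", tid)]] <- piece
  }
  coord_cols <- c("x_um", "y_um")
  if (any(vapply(pieces, function(p) any(p$z_um != 0, na.rm = TRUE), logical(1))))
    coord_cols <- c(coord_cols, "z_um")
  fi <- xml2::xml_attr(xml2::xml_find_first(doc, ".//Settings/ImageData"),
                       "timeinterval")
  if (!is.na(fi) && as.numeric(fi) > 0) frame_interval <- as.numeric(fi)
  out <- build_track_list(pieces, coord_cols, frame_interval)
  settings <- xml2::xml_find_first(doc, ".//Settings")
  if (!inherits(settings, "xml_missing"))
    attr(out, "settings") <- as.character(settings)
  out
}

#' Write tracks to CSV
#'
#' Writes a list of trajectories in the schema [read_tracks()] consumes:
#' `track_id, frame, t_min, x_um, y_um[, z_um]`.
#'
#' @param tracks A list of [trajectory()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "trajectory")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    df <- data.frame(track_id = tr$track_id, frame = tr$frames,
                     t_min = tr$frames * tr$frame_interval,
                     stringsAsFactors = FALSE)
    pos <- tr$positions
    df$x_um <- pos[, 1]; df$y_um <- pos[, 2]
    if (ncol(pos) == 3) df$z_um <- pos[, 3]
    df
  })
  has_z <- vapply(rows, function(r) "z_um" %in% names(r), logical(1))
  if (any(has_z) && !all(has_z))
    rows <- lapply(rows, function(r) { if (!"z_um" %in% names(r)) r$z_um <- 0; r })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
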