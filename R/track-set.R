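#' @importFrom data.table data.table fread fwrite := .N setDF setDT rbindlist
NULL

#' Construct a set of particle tracks
#'
#' The central container for single-particle-tracking data.  Positions are
#' stored per track as an n x 2 matrix of (x, y) coordinates in nm sampled
#' at consecutive frames; bookkeeping tables record per-track and per-cell
#' provenance (cell, imaging session, day).
#'
#' @param positions Named list of numeric matrices (columns x, y, nm), one
#'   per track, named by `track_id`.
#' @param tracks data.frame with columns `track_id`, `cell_id`,
#'   `session_id`, `day_id` (one row per track).
#' @param cells data.frame with columns `cell_id`, `session_id`, `day_id`,
#'   `length_nm`, `width_nm`.  Lengths/widths may be NA for experimental
#'   data that was never registered to a cell box; simulation requires them.
#' @param frame_interval_ms Time between consecutive frames, ms.
#' @param provenance Free-text metadata (character vector).
#' @return An object of class `track_set`.
#' @export
track_set <- function(positions, tracks, cells, frame_interval_ms = 10,
                      provenance = character()) {
  tracks <- as.data.frame(tracks, stringsAsFactors = FALSE)
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  tracks$n_points <- vapply(positions[as.character(tracks$track_id)],
                            nrow, integer(1))
  positions <- lapply(positions, function(m) {
    dimnames(m) <- list(NULL, c("x", "y"))
    m
  })
  ts <- structure(list(positions = positions, tracks = tracks, cells = cells,
                       frame_interval_ms = frame_interval_ms,
                       provenance = provenance),
                  class = "track_set")
  validate_track_set(ts)
  ts
}

#' Validate a track_set
#'
#' Checks the container invariants: finite coordinates, positive frame
#' interval, every track resolving to a known cell, and session/day labels
#' consistent between tracks and their cells.
#'
#' @param ts A `track_set`.
#' @return `ts`, invisibly; errors on violation.
#' @export
validate_track_set <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  if (!is.numeric(ts$frame_interval_ms) || ts$frame_interval_ms <= 0)
    stop("frame_interval_ms must be > 0")
  req_t <- c("track_id", "cell_id", "session_id", "day_id", "n_points")
  if (!all(req_t %in% names(ts$tracks)))
    stop("tracks table missing column(s): ",
         paste(setdiff(req_t, names(ts$tracks)), collapse = ", "))
  req_c <- c("cell_id", "session_id", "day_id", "length_nm", "width_nm")
  if (!all(req_c %in% names(ts$cells)))
    stop("cells table missing column(s): ",
         paste(setdiff(req_c, names(ts$cells)), collapse = ", "))
  if (anyDuplicated(ts$tracks$track_id))
    stop("duplicate track_id in tracks table")
  if (anyDuplicated(ts$cells$cell_id))
    stop("duplicate cell_id in cells table")
  if (!setequal(names(ts$positions), as.character(ts$tracks$track_id)))
    stop("positions list and tracks table disagree on track ids")
  bad <- !(ts$tracks$cell_id %in% ts$cells$cell_id)
  if (any(bad))
    stop("track(s) reference unknown cell_id: ",
         paste(unique(ts$tracks$cell_id[bad]), collapse = ", "))
  for (id in names(ts$positions)) {
    m <- ts$positions[[id]]
    if (!is.matrix(m) || ncol(m) != 2L)
      stop("positions for track ", id, " must be an n x 2 matrix")
    if (nrow(m) < 1L) stop("track ", id, " has no points")
    if (!all(is.finite(m))) stop("non-finite coordinate in track ", id)
  }
  # session/day labels of each track must match its cell's
  idx <- match(ts$tracks$cell_id, ts$cells$cell_id)
  if (any(ts$tracks$session_id != ts$cells$session_id[idx]) ||
      any(ts$tracks$day_id != ts$cells$day_id[idx]))
    stop("track session/day labels inconsistent with their cell's")
  with_len <- !is.na(ts$cells$length_nm)
  if (any(ts$cells$length_nm[with_len] <= 0))
    stop("cell length_nm must be > 0")
  with_w <- !is.na(ts$cells$width_nm)
  if (any(ts$cells$width_nm[with_w] <= 0))
    stop("cell width_nm must be > 0")
  invisible(ts)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks in %d cells, frame interval %g ms\n",
              nrow(x$tracks), nrow(x$cells), x$frame_interval_ms))
  if (length(x$provenance)) cat("  provenance:", x$provenance[1], "\n")
  invisible(x)
}

#' Number of tracks in a track_set
#' @param ts A `track_set`.
#' @return Integer count.
#' @export
n_tracks <- function(ts) nrow(ts$tracks)

# ---------------------------------------------------------------------------
# Tabular I/O

.canonical_cols <- c("track_id", "cell_id", "session_id", "day_id",
                     "frame", "x_nm", "y_nm")

#' Read particle tracks from a tabular file
#'
#' Supported dialects:
#' \describe{
#'   \item{canonical}{Tab- or comma-separated with header columns
#'     `track_id, cell_id, session_id, day_id, frame, x_nm, y_nm`
#'     (frame 0-based, one row per track-frame), plus an optional cell table
#'     (`cell_id, session_id, day_id, length_nm, width_nm`).}
#'   \item{mosaic}{A MOSAIC-ParticleTracker-style export with columns
#'     `Trajectory, Frame, x, y` in pixels.  Because the pixel size and
#'     frame interval are not recorded in such exports, `pixel_size_nm` and
#'     `frame_interval_ms` are mandatory — they are never guessed.}
#' }
#'
#' Tracks must be gap-free: frames within a track must be consecutive.
#' Unrecognized columns are preserved in the `provenance` attribute.
#'
#' @param path Path to the track table.
#' @param dialect `"canonical"` or `"mosaic"`.
#' @param cells_path Optional path to the cell table (canonical dialect).
#'   Defaults to `<path minus extension>_cells.<ext>` when that file exists.
#' @param pixel_size_nm,frame_interval_ms Unit conversions, required for the
#'   mosaic dialect.
#' @param cell_id,session_id,day_id Labels applied to every track of a
#'   mosaic export (one movie = one cell).
#' @return A [track_set()].
#' @export
read_tracks <- function(path, dialect = c("canonical", "mosaic"),
                        cells_path = NULL,
                        pixel_size_nm = NULL, frame_interval_ms = NULL,
                        cell_id = "cell1", session_id = "s1", day_id = "d1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "mosaic") {
    if (is.null(pixel_size_nm) || is.null(frame_interval_ms))
      stop("mosaic dialect requires explicit pixel_size_nm and ",
           "frame_interval_ms; these conversion factors are never guessed")
    raw <- fread(path)
    need <- c("Trajectory", "Frame", "x", "y")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("mosaic file missing required column(s): ",
           paste(miss, collapse = ", "))
    tab <- data.table(track_id = as.character(raw$Trajectory),
                      cell_id = cell_id, session_id = session_id,
                      day_id = day_id, frame = as.integer(raw$Frame),
                      x_nm = raw$x * pixel_size_nm,
                      y_nm = raw$y * pixel_size_nm)
    cells <- data.frame(cell_id = cell_id, session_id = session_id,
                        day_id = day_id, length_nm = NA_real_,
                        width_nm = NA_real_, stringsAsFactors = FALSE)
    fi <- frame_interval_ms
    extra <- setdiff(names(raw), need)
  } else {
    tab <- fread(path)
    miss <- setdiff(.canonical_cols, names(tab))
    if (length(miss))
      stop("canonical track file missing required column(s): ",
           paste(miss, collapse = ", "))
    extra <- setdiff(names(tab), .canonical_cols)
    for (col in c("track_id", "cell_id", "session_id", "day_id"))
      tab[[col]] <- as.character(tab[[col]])
    fi <- if (is.null(frame_interval_ms)) 10 else frame_interval_ms
    if (is.null(cells_path)) {
      guess <- sub("(\\.[^.]*)?$", "_cells\\1", path)
      if (file.exists(guess)) cells_path <- guess
    }
    if (!is.null(cells_path)) {
      cells <- setDF(fread(cells_path))
      for (col in c("cell_id", "session_id", "day_id"))
        cells[[col]] <- as.character(cells[[col]])
    } else {
      u <- unique(tab[, c("cell_id", "session_id", "day_id")])
      cells <- data.frame(u, length_nm = NA_real_, width_nm = NA_real_,
                          stringsAsFactors = FALSE)
    }
  }
  sp <- split(seq_len(nrow(tab)), tab$track_id)
  # preserve first-appearance order of track ids
  sp <- sp[unique(tab$track_id)]
  positions <- vector("list", length(sp))
  names(positions) <- names(sp)
  meta <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    rows <- sp[[i]]
    fr <- tab$frame[rows]
    o <- order(fr)
    rows <- rows[o]; fr <- fr[o]
    if (length(fr) > 1L && any(diff(fr) != 1L))
      stop("non-uniform frame spacing (gap) within track ", names(sp)[i])
    positions[[i]] <- cbind(x = tab$x_nm[rows], y = tab$y_nm[rows])
    meta[[i]] <- data.frame(track_id = names(sp)[i],
                            cell_id = tab$cell_id[rows[1]],
                            session_id = tab$session_id[rows[1]],
                            day_id = tab$day_id[rows[1]],
                            stringsAsFactors = FALSE)
  }
  tracks <- do.call(rbind, meta)
  prov <- c(sprintf("read_tracks: %s (%s dialect)", path, dialect),
            if (length(extra))
              sprintf("unrecognized columns preserved: %s",
                      paste(extra, collapse = ", ")))
  track_set(positions, tracks, cells, frame_interval_ms = fi,
            provenance = prov)
}

#' Write particle tracks to the canonical tabular format
#'
#' Lossless: coordinates are serialized with 17 significant digits so that
#' `read_tracks(write_tracks(ts))` reproduces positions bit-exactly.
#'
#' @param ts A `track_set`.
#' @param path Output path for the track table (TSV).
#' @param cells_path Output path for the cell table; defaults to
#'   `<path minus extension>_cells.<ext>`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path, cells_path = NULL) {
  validate_track_set(ts)
  if (is.null(cells_path)) cells_path <- sub("(\\.[^.]*)?$", "_cells\\1", path)
  rows <- lapply(seq_len(nrow(ts$tracks)), function(i) {
    id <- as.character(ts$tracks$track_id[i])
    m <- ts$positions[[id]]
    data.table(track_id = id,
               cell_id = ts$tracks$cell_id[i],
               session_id = ts$tracks$session_id[i],
               day_id = ts$tracks$day_id[i],
               frame = seq_len(nrow(m)) - 1L,
               x_nm = sprintf("%.17g", m[, 1]),
               y_nm = sprintf("%.17g", m[, 2]))
  })
  out <- if (length(rows)) rbindlist(rows) else
    data.table(track_id = character(), cell_id = character(),
               session_id = character(), day_id = character(),
               frame = integer(), x_nm = character(), y_nm = character())
  fwrite(out, path, sep = "\t", quote = FALSE)
  cells <- ts$cells
  cells$length_nm <- sprintf("%.17g", cells$length_nm)
  cells$width_nm <- sprintf("%.17g", cells$width_nm)
  fwrite(cells, cells_path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Remove tracks shorter than a minimum number of points
#'
#' Tracks shorter than `min_points` time points are removed from further
#' analysis (default 10).  Cells emptied of all their tracks are retained in
#' the cell table, flagged in the `empty_after_filter` column, so that
#' cell-wise bookkeeping keeps its one-to-one mapping to the original set.
#'
#' @param ts A `track_set`.
#' @param min_points Minimum track length in points (>= 2).
#' @return A filtered `track_set`.
#' @export
filter_min_length <- function(ts, min_points = 10) {
  validate_track_set(ts)
  stopifnot(min_points >= 2)
  keep <- ts$tracks$n_points >= min_points
  out <- ts
  out$tracks <- ts$tracks[keep, , drop = FALSE]
  rownames(out$tracks) <- NULL
  out$positions <- ts$positions[as.character(out$tracks$track_id)]
  out$cells$empty_after_filter <-
    !(ts$cells$cell_id %in% out$tracks$cell_id)
  out$provenance <- c(ts$provenance,
                      sprintf("filter_min_length: min_points=%d, %d/%d kept",
                              min_points, sum(keep), length(keep)))
  out
}

#' Extract the experiment-statistics ledger from a track set
#'
#' The ledger records, per cell, the cell geometry and the duration (in
#' frames) of every track — exactly the information a doppelganger
#' simulation replicates one-to-one.  Durations are listed in the order the
#' tracks appear in the tracks table, keyed by track id, so that
#' `extract_experiment_stats(run_doppelganger(S, ...))` equals `S`.
#'
#' @param ts A `track_set`.
#' @return An object of class `experiment_stats`: list with `cells`
#'   (data.frame `cell_id, session_id, day_id, length_nm`), `durations`
#'   (named list of named integer vectors, frames per track, keyed by cell
#'   then track id) and `frame_interval_ms`.
#' @export
extract_experiment_stats <- function(ts) {
  validate_track_set(ts)
  if (any(is.na(ts$cells$length_nm)))
    stop("all cells need a length_nm to build an experiment ledger")
  cells <- data.frame(cell_id = as.character(ts$cells$cell_id),
                      session_id = as.character(ts$cells$session_id),
                      day_id = as.character(ts$cells$day_id),
                      length_nm = as.numeric(ts$cells$length_nm),
                      stringsAsFactors = FALSE)
  durations <- lapply(cells$cell_id, function(cid) {
    sel <- ts$tracks$cell_id == cid
    d <- as.integer(ts$tracks$n_points[sel])
    names(d) <- as.character(ts$tracks$track_id[sel])
    d
  })
  names(durations) <- cells$cell_id
  structure(list(cells = cells, durations = durations,
                 frame_interval_ms = as.numeric(ts$frame_interval_ms)),
            class = "experiment_stats")
}

#' @export
print.experiment_stats <- function(x, ...) {
  nt <- sum(lengths(x$durations))
  cat(sprintf("experiment_stats: %d cells, %d tracks, dt = %g ms\n",
              nrow(x$cells), nt, x$frame_interval_ms))
  invisible(x)
}

#' Per-frame step lengths of all tracks
#'
#' Euclidean 2D displacement magnitude between every pair of consecutive
#' frames, pooled over tracks.
#'
#' @param ts A `track_set`.
#' @return Numeric vector of step lengths (nm), one per consecutive frame
#'   pair per track.
#' @export
step_lengths <- function(ts) {
  validate_track_set(ts)
  if (n_tracks(ts) == 0L) stop("step_lengths() needs a non-empty track_set")
  unlist(lapply(ts$positions, function(m) {
    if (nrow(m) < 2L) return(numeric(0))
    sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
  }), use.names = FALSE)
}
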