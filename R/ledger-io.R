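#' Read and write experiment-statistics ledgers
#'
#' A ledger is serialized as a single TSV with one row per track (columns
#' `cell_id, session_id, day_id, length_nm, frame_interval_ms, track_id,
#' duration_frames`); cells without tracks keep one row with an empty
#' track id.
#'
#' @param stats An `experiment_stats` object.
#' @param path Output path.
#' @return `path` invisibly (write); an `experiment_stats` (read).
#' @export
write_ledger <- function(stats, path) {
  stopifnot(inherits(stats, "experiment_stats"))
  rows <- lapply(seq_len(nrow(stats$cells)), function(i) {
    cell <- stats$cells[i, ]
    durs <- stats$durations[[cell$cell_id]]
    if (!length(durs))
      return(data.table(cell_id = cell$cell_id,
                        session_id = cell$session_id,
                        day_id = cell$day_id,
                        length_nm = sprintf("%.17g", cell$length_nm),
                        frame_interval_ms = stats$frame_interval_ms,
                        track_id = "", duration_frames = NA_integer_))
    data.table(cell_id = cell$cell_id, session_id = cell$session_id,
               day_id = cell$day_id,
               length_nm = sprintf("%.17g", cell$length_nm),
               frame_interval_ms = stats$frame_interval_ms,
               track_id = names(durs), duration_frames = as.integer(durs))
  })
  fwrite(rbindlist(rows), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- fread(path)
  need <- c("cell_id", "session_id", "day_id", "length_nm",
            "frame_interval_ms", "track_id", "duration_frames")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ledger file missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("cell_id", "session_id", "day_id", "track_id"))
    tab[[col]] <- as.character(tab[[col]])
  ucell <- !duplicated(tab$cell_id)
  cells <- data.frame(cell_id = tab$cell_id[ucell],
                      session_id = tab$session_id[ucell],
                      day_id = tab$day_id[ucell],
                      length_nm = as.numeric(tab$length_nm[ucell]),
                      stringsAsFactors = FALSE)
  durations <- lapply(cells$cell_id, function(cid) {
    sel <- tab$cell_id == cid & !is.na(tab$duration_frames) &
      tab$track_id != ""
    d <- as.integer(tab$duration_frames[sel])
    names(d) <- tab$track_id[sel]
    d
  })
  names(durations) <- cells$cell_id
  structure(list(cells = cells, durations = durations,
                 frame_interval_ms = as.numeric(tab$frame_interval_ms[1])),
            class = "experiment_stats")
}
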