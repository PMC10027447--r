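#' Configuration of the synthetic experiment generator
#'
#' The defaults emulate the printed summary of the reference data set:
#' 145 cells imaged in 5 sessions over 3 days, about 25 +/- 10 tracks per
#' cell, exponentially decaying track durations with mean 273 ms and a
#' 10-frame minimum at 10 ms framing, and a roughly two-fold range of cell
#' lengths (7-14 um).
#'
#' @param n_cells Number of cells (default 145).
#' @param tracks_per_cell_mean,tracks_per_cell_sd Per-cell track counts:
#'   rounded truncated normal, minimum 1 (defaults 25 and 10).
#' @param duration_mean_ms Mean track duration of the truncated
#'   exponential (default 273 ms; the underlying rate is solved so that
#'   the truncated distribution has this mean).
#' @param duration_min_ms,duration_max_ms Truncation bounds: the 10-frame
#'   minimum (100 ms) and the 10 s acquisition window.
#' @param frame_interval_ms Frame interval (default 10 ms).
#' @param cell_length_range_nm Uniform range of long-axis lengths
#'   (default 7000-14000 nm).
#' @param n_sessions,n_days Imaging sessions and days; cells are assigned
#'   round-robin to sessions and sessions round-robin to days.
#' @param seed RNG seed.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_cells = 145, tracks_per_cell_mean = 25,
                         tracks_per_cell_sd = 10,
                         duration_mean_ms = 273, duration_min_ms = 100,
                         duration_max_ms = 10000, frame_interval_ms = 10,
                         cell_length_range_nm = c(7000, 14000),
                         n_sessions = 5, n_days = 3, seed = 1) {
  stopifnot(n_cells >= 1, tracks_per_cell_mean > 0, tracks_per_cell_sd >= 0,
            duration_min_ms < duration_mean_ms,
            duration_mean_ms < duration_max_ms,
            frame_interval_ms > 0,
            duration_min_ms >= 10 * frame_interval_ms,
            length(cell_length_range_nm) == 2,
            all(cell_length_range_nm > 0),
            n_sessions >= 1, n_days >= 1)
  structure(as.list(environment()), class = "synth_config")
}

# rate of an exponential truncated to [a, b] whose mean equals m
.trunc_exp_rate <- function(m, a, b) {
  tmean <- function(rate) {
    # E[X | a <= X <= b] for X ~ Exp(rate)
    za <- exp(-rate * a); zb <- exp(-rate * b)
    (a * za - b * zb + (za - zb) / rate) / (za - zb)
  }
  stats::uniroot(function(r) tmean(r) - m,
                 lower = 1e-6, upper = 1, tol = 1e-12)$root
}

# inverse-CDF sampling of the truncated exponential
.rtrunc_exp <- function(n, rate, a, b) {
  u <- stats::runif(n)
  Fa <- stats::pexp(a, rate); Fb <- stats::pexp(b, rate)
  stats::qexp(Fa + u * (Fb - Fa), rate)
}

#' Generate a synthetic experiment-statistics ledger
#'
#' Per-cell track counts are a rounded truncated normal (minimum 1);
#' durations are i.i.d. truncated-exponential draws converted to whole
#' frames (at least 10); cell lengths are uniform over the configured
#' range; cells are assigned round-robin to sessions and sessions to days.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return An `experiment_stats` ledger.
#' @export
generate_experiment_stats <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  n <- cfg$n_cells
  counts <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      k <- round(stats::rnorm(1, cfg$tracks_per_cell_mean,
                              cfg$tracks_per_cell_sd))
      if (k >= 1) { counts[i] <- k; break }
    }
  }
  session <- ((seq_len(n) - 1L) %% cfg$n_sessions) + 1L
  day <- ((session - 1L) %% cfg$n_days) + 1L
  lengths_nm <- stats::runif(n, cfg$cell_length_range_nm[1],
                             cfg$cell_length_range_nm[2])
  rate <- .trunc_exp_rate(cfg$duration_mean_ms, cfg$duration_min_ms,
                          cfg$duration_max_ms)
  cells <- data.frame(
    cell_id = sprintf("cell%03d", seq_len(n)),
    session_id = sprintf("s%d", session),
    day_id = sprintf("d%d", day),
    length_nm = lengths_nm, stringsAsFactors = FALSE)
  durations <- vector("list", n)
  names(durations) <- cells$cell_id
  tr <- 0L
  dt <- cfg$frame_interval_ms
  max_frames <- as.integer(floor(cfg$duration_max_ms / dt))
  for (i in seq_len(n)) {
    d_ms <- .rtrunc_exp(counts[i], rate, cfg$duration_min_ms,
                        cfg$duration_max_ms)
    frames <- pmin(pmax(as.integer(round(d_ms / dt)), 10L), max_frames)
    names(frames) <- sprintf("t%05d", tr + seq_along(frames))
    tr <- tr + counts[i]
    durations[[i]] <- frames
  }
  structure(list(cells = cells, durations = durations,
                 frame_interval_ms = dt),
            class = "experiment_stats")
}

#' Reference distribution of apparent diffusivities
#'
#' Hierarchical log-normal model matching the printed summaries of the
#' reference experiment: track-wise log10 diffusivities centred on a
#' configurable median with total SD `sigma_track = log10(fold_track) / 5`
#' split into a cell-level (extrinsic) and a track-level (intrinsic)
#' component.
#'
#' @param track_median_um2_s Track-wise median diffusivity (default
#'   0.29 um^2/s).
#' @param fold_track Track-wise fold range (default 392; sets sigma).
#' @param extrinsic_share Fraction of the track-wise log-variance carried
#'   by the cell level (default 0.2, i.e. an 80/20 intrinsic/extrinsic
#'   split).
#' @param seed RNG seed.
#' @return A `reference_config` object.
#' @export
reference_config <- function(track_median_um2_s = 0.29, fold_track = 392,
                             extrinsic_share = 0.2, seed = 1) {
  stopifnot(track_median_um2_s > 0, fold_track >= 1,
            extrinsic_share >= 0, extrinsic_share <= 1)
  structure(list(track_median_um2_s = track_median_um2_s,
                 fold_track = fold_track,
                 extrinsic_share = extrinsic_share,
                 seed = as.integer(seed)),
            class = "reference_config")
}

#' Generate reference per-track diffusivities for a ledger
#'
#' For every track in the ledger, draws
#' `log10(d_app) = mu_log + cell_effect + track_effect` with the cell
#' effect normal with variance `extrinsic_share * sigma_track^2` and the
#' track effect carrying the remainder.  Values are log10 diffusivities in
#' nm^2/ms (internal canonical units; 0.29 um^2/s = 290 nm^2/ms).
#'
#' @param stats An `experiment_stats` ledger (supplies the cell/track
#'   structure and labels).
#' @param cfg A [reference_config()].
#' @return data.frame with `track_id`, `cell_id`, `session_id`, `day_id`,
#'   `log10_d_app` (nm^2/ms) and `d_app` (nm^2/ms).
#' @export
generate_reference_diffusivities <- function(stats,
                                             cfg = reference_config()) {
  stopifnot(inherits(stats, "experiment_stats"),
            inherits(cfg, "reference_config"))
  if (!nrow(stats$cells)) stop("empty ledger")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  mu_log <- log10(um2s_to_nm2ms(cfg$track_median_um2_s))
  sigma <- log10(cfg$fold_track) / 5
  s_cell <- sigma * sqrt(cfg$extrinsic_share)
  s_track <- sigma * sqrt(1 - cfg$extrinsic_share)
  rows <- vector("list", nrow(stats$cells))
  for (i in seq_len(nrow(stats$cells))) {
    cell <- stats$cells[i, ]
    durs <- stats$durations[[cell$cell_id]]
    nt <- length(durs)
    if (!nt) { rows[[i]] <- NULL; next }
    eff_c <- stats::rnorm(1, 0, s_cell)
    lv <- mu_log + eff_c + stats::rnorm(nt, 0, s_track)
    rows[[i]] <- data.frame(track_id = names(durs),
                            cell_id = cell$cell_id,
                            session_id = cell$session_id,
                            day_id = cell$day_id,
                            log10_d_app = lv, d_app = 10^lv,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
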