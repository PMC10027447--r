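#' Reflect proposed coordinates back into an interval
#'
#' Implements reflecting boundary conditions on [lower, upper] by repeated
#' folding: a proposal of -50 on [0, 10000] maps to 50, a proposal of 3100
#' on [0, 3000] maps to 2900, and -3100 maps to 2900 (two reflections).
#'
#' @param v Numeric vector of proposed coordinates.
#' @param upper Upper boundary (lower is 0).
#' @return Reflected coordinates inside [0, upper].
#' @export
reflect_into_box <- function(v, upper) {
  stopifnot(upper > 0)
  r <- v %% (2 * upper)
  ifelse(r > upper, 2 * upper - r, r)
}

#' Simulate one Brownian track inside a rectangular cell
#'
#' Fixed-timestep Brownian dynamics: each timestep draws independent
#' per-axis Gaussian displacements with standard deviation
#' xi = sqrt(2 k_B T dt / gamma) evaluated from the viscosity at the step's
#' starting position, and proposed positions are folded back into the
#' [0, L] x [0, W] box by (possibly repeated) reflection.  The initial
#' position is uniform in the box unless `start` is given.  Uses the
#' current RNG state; seed outside for reproducibility.
#'
#' @param field A `viscosity_field` (carries the cell geometry).
#' @param n_steps Number of timesteps (>= 1); the track has `n_steps + 1`
#'   positions.
#' @param p A [physical_params()].
#' @param start Optional length-2 start position (nm).
#' @return An (n_steps + 1) x 2 matrix of positions (nm).
#' @export
simulate_track <- function(field, n_steps, p = physical_params(),
                           start = NULL) {
  stopifnot(n_steps >= 1)
  L <- field$length_nm; W <- field$width_nm
  if (is.null(start)) start <- c(stats::runif(1, 0, L), stats::runif(1, 0, W))
  zx <- stats::rnorm(n_steps)
  zy <- stats::rnorm(n_steps)
  if (field$mode == "single") {
    xi <- brownian_step_sd(p, field$values)
    x <- reflect_into_box(start[1] + cumsum(xi * zx), L)
    y <- reflect_into_box(start[2] + cumsum(xi * zy), W)
    return(cbind(x = c(start[1], x), y = c(start[2], y)))
  }
  # heterogeneous field: step SD depends on the current domain
  xi_dom <- sqrt(2 * stokes_einstein_diffusivity(p, field$values) * p$dt_ms)
  xb <- field$x_breaks; yb <- field$y_breaks
  nxd <- length(xb) - 1L; nyd <- length(yb) - 1L
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 2L,
                dimnames = list(NULL, c("x", "y")))
  cx <- start[1]; cy <- start[2]
  out[1L, ] <- c(cx, cy)
  for (i in seq_len(n_steps)) {
    ix <- min(findInterval(cx, xb), nxd)
    iy <- min(findInterval(cy, yb), nyd)
    xi <- xi_dom[iy, ix]
    px <- cx + xi * zx[i]
    py <- cy + xi * zy[i]
    rx <- px %% (2 * L); if (rx > L) rx <- 2 * L - rx
    ry <- py %% (2 * W); if (ry > W) ry <- 2 * W - ry
    cx <- rx; cy <- ry
    out[i + 1L, ] <- c(cx, cy)
  }
  out
}

# derive reproducible per-unit seeds from a root seed without disturbing
# the caller's RNG state
.substream_seeds <- function(root, n) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(root)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a doppelganger simulation of an experiment ledger
#'
#' One simulated cell per ledger cell (long-axis length from the ledger,
#' short-axis width `width_nm`), one simulated track per ledger track with
#' exactly the ledger's duration in frames, and cell/session/day labels
#' copied verbatim — so that
#' `extract_experiment_stats(run_doppelganger(S, ...))` equals `S`.
#' The run is fully deterministic given `cfg$seed`: the root seed expands
#' to per-cell and per-track substreams, making every track reproducible
#' independently of execution order.
#'
#' Each experimental track is contiguous from its own starting frame, so a
#' simulated track of the same number of frames is statistically
#' equivalent; tracks are simulated directly at their ledger duration
#' (equivalent to simulating to the longest duration and pruning to the
#' leading frames).
#'
#' @param stats An `experiment_stats` ledger.
#' @param cfg A [model_config()].
#' @param p A [physical_params()]; `p$dt_ms` must equal the ledger's frame
#'   interval.
#' @param width_nm Short-axis width of every simulated cell (default
#'   3000 nm).
#' @return A `track_set` whose cells table carries the per-cell mean
#'   viscosity in `mean_viscosity` (pN ms/nm^2).
#' @export
run_doppelganger <- function(stats, cfg, p = physical_params(),
                             width_nm = 3000) {
  stopifnot(inherits(stats, "experiment_stats"))
  if (!isTRUE(all.equal(p$dt_ms, stats$frame_interval_ms)))
    stop("p$dt_ms (", p$dt_ms, ") must equal the ledger frame interval (",
         stats$frame_interval_ms, ")")
  n_cells <- nrow(stats$cells)
  if (n_cells == 0L) stop("empty ledger")
  cell_seeds <- .substream_seeds(cfg$seed, n_cells)
  positions <- list()
  track_rows <- vector("list", n_cells)
  mean_visc <- numeric(n_cells)
  old <- .save_rng(); on.exit(.restore_rng(old))
  for (ci in seq_len(n_cells)) {
    cell <- stats$cells[ci, ]
    durs <- stats$durations[[cell$cell_id]]
    set.seed(cell_seeds[ci])
    field <- build_viscosity_field(
      data.frame(length_nm = cell$length_nm, width_nm = width_nm),
      cfg, p)
    mean_visc[ci] <- field$cell_mean_viscosity
    nt <- length(durs)
    if (nt) {
      track_seeds <- sample.int(.Machine$integer.max - 1L, nt)
      for (ti in seq_len(nt)) {
        set.seed(track_seeds[ti])
        positions[[names(durs)[ti]]] <-
          simulate_track(field, n_steps = durs[ti] - 1L, p = p)
      }
      track_rows[[ci]] <- data.frame(
        track_id = names(durs), cell_id = cell$cell_id,
        session_id = cell$session_id, day_id = cell$day_id,
        stringsAsFactors = FALSE)
    }
  }
  tracks <- do.call(rbind, track_rows)
  cells <- data.frame(cell_id = stats$cells$cell_id,
                      session_id = stats$cells$session_id,
                      day_id = stats$cells$day_id,
                      length_nm = stats$cells$length_nm,
                      width_nm = width_nm,
                      mean_viscosity = mean_visc,
                      stringsAsFactors = FALSE)
  track_set(positions, tracks, cells,
            frame_interval_ms = stats$frame_interval_ms,
            provenance = sprintf(
              "simulation: doppelganger %s model, seed %d", cfg$model,
              cfg$seed))
}
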