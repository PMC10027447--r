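#' Summary targets for model calibration
#'
#' The three statistics a calibrated model must reproduce: the median
#' order of magnitude of the track-wise apparent diffusivities (mean of
#' log10 values), their SD, and the SD of the per-cell means of the log10
#' values (the cell-wise spread).  The two SDs are the monotone
#' equivalents of the track-wise and cell-wise variances.
#'
#' @param log10_values Track-wise log10 diffusivities (nm^2/ms).
#' @param cell_ids Cell label per value.
#' @return list with `mu_log`, `sigma_track`, `sigma_cell`.
#' @export
calibration_targets <- function(log10_values, cell_ids) {
  keep <- is.finite(log10_values)
  lv <- log10_values[keep]; cid <- as.character(cell_ids)[keep]
  stopifnot(length(lv) >= 2)
  cm <- tapply(lv, cid, mean)
  list(mu_log = mean(lv), sigma_track = stats::sd(lv),
       sigma_cell = stats::sd(as.numeric(cm)))
}

# evaluate the calibration statistics of one parameter point by averaging
# over replicate doppelganger simulations (common random numbers: the
# replicate seeds are fixed across evaluations)
.calib_stats <- function(stats, theta, domain_size_nm, p, rep_seeds,
                         n_lags, tau0) {
  res <- matrix(NA_real_, nrow = length(rep_seeds), ncol = 3)
  for (r in seq_along(rep_seeds)) {
    cfg <- model_config("combined",
                        mean_visc_rel_water = theta[1],
                        sigma_cell = theta[2], sigma_spatial = theta[3],
                        domain_size_nm = domain_size_nm,
                        seed = rep_seeds[r])
    sim <- run_doppelganger(stats, cfg, p)
    fits <- fit_hierarchy(sim, "track", n_lags = n_lags, tau0 = tau0)
    ok <- fits$status == "ok" & is.finite(fits$d_app) & fits$d_app > 0
    tg <- calibration_targets(log10(fits$d_app[ok]), fits$cell_id[ok])
    res[r, ] <- c(tg$mu_log, tg$sigma_track, tg$sigma_cell)
  }
  list(mean = colMeans(res), spread = apply(res, 2, stats::sd))
}

#' Calibrate a combined-heterogeneity model to summary targets
#'
#' Finds the population mean viscosity and the two log-normal shape
#' parameters (cell-level, domain-level) for which doppelganger
#' simulations of `stats` reproduce three target statistics: the median
#' log10 apparent diffusivity, the track-wise log10 SD, and the cell-wise
#' (per-cell mean) log10 SD.  The declared loss is the sum of squared
#' mismatches of those three statistics (all in log10 units).
#'
#' The search exploits an exact scaling: diffusivity is inversely
#' proportional to viscosity, so rescaling the mean viscosity shifts the
#' median log10 diffusivity without touching the spreads (up to the water
#' floor, negligible at the default parameters).  The two shapes are
#' optimised by a coarse grid followed by Nelder-Mead on the spread
#' mismatch, and the mean viscosity is then solved directly from the
#' median offset.  Replicate simulations use fixed seeds (common random
#' numbers), so the whole procedure is deterministic given `seed`.
#'
#' @param stats An `experiment_stats` ledger.
#' @param domain_size_nm Spatial domain size Lambda, nm.
#' @param targets list with `mu_log`, `sigma_track`, `sigma_cell` (see
#'   [calibration_targets()]).
#' @param p A [physical_params()].
#' @param search list of search options: `start` (length-2, initial
#'   shapes), `lower`/`upper` (shape bounds), `grid` (logical: coarse
#'   pre-scan), `maxit` (Nelder-Mead iterations), `n_rep` (replicate
#'   simulations per evaluation), `tol` (loss below which the result is
#'   declared converged).
#' @param n_lags,tau0 MSD fit window.
#' @param seed Root seed for the replicate substreams.
#' @return A `calibration_result`: list with `config` (the calibrated
#'   [model_config()]), `loss`, `achieved` (the three statistics at the
#'   optimum), `targets`, `replicate_spread`, `converged`, `n_eval`.
#' @export
calibrate_model <- function(stats, domain_size_nm = 1000, targets,
                            p = physical_params(), search = list(),
                            n_lags = 7, tau0 = 100, seed = 1) {
  stopifnot(all(c("mu_log", "sigma_track", "sigma_cell") %in%
                  names(targets)),
            all(vapply(targets, is.finite, logical(1))))
  opts <- utils::modifyList(
    list(start = c(0.45, 0.85), lower = c(0, 0), upper = c(2, 3),
         grid = TRUE, maxit = 40, n_rep = 2, tol = 1e-3,
         mean_start = 40), search)
  rep_seeds <- .substream_seeds(seed, opts$n_rep)
  tgt <- c(targets$mu_log, targets$sigma_track, targets$sigma_cell)
  n_eval <- 0L
  cache <- new.env(parent = emptyenv())
  eval_shapes <- function(sh, mean_visc) {
    sh <- pmin(pmax(sh, opts$lower), opts$upper)
    key <- paste(signif(c(mean_visc, sh), 10), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    st <- .calib_stats(stats, c(mean_visc, sh), domain_size_nm, p,
                       rep_seeds, n_lags, tau0)
    n_eval <<- n_eval + 1L
    cache[[key]] <- st
    st
  }
  shape_loss <- function(sh, mean_visc) {
    st <- eval_shapes(sh, mean_visc)$mean
    (st[2] - tgt[2])^2 + (st[3] - tgt[3])^2
  }
  mean_visc <- opts$mean_start
  # coarse grid pre-scan for a robust Nelder-Mead start
  start <- opts$start
  if (isTRUE(opts$grid)) {
    grid <- expand.grid(sc = unique(pmin(pmax(c(0.1, 0.45, 0.8),
                                              opts$lower[1]),
                                         opts$upper[1])),
                        ss = unique(pmin(pmax(c(0.4, 0.85, 1.3),
                                              opts$lower[2]),
                                         opts$upper[2])))
    gl <- apply(grid, 1, function(g) shape_loss(as.numeric(g), mean_visc))
    start <- as.numeric(grid[which.min(gl), ])
  }
  o <- stats::optim(start, shape_loss, mean_visc = mean_visc,
                    method = "Nelder-Mead",
                    control = list(maxit = opts$maxit, reltol = 1e-4))
  shapes <- pmin(pmax(o$par, opts$lower), opts$upper)
  # solve the mean viscosity from the median offset (D ~ 1/eta), then
  # polish once in case the floor clipping moved the spreads slightly
  for (pass in 1:2) {
    st <- eval_shapes(shapes, mean_visc)
    mean_visc <- mean_visc * 10^(st$mean[1] - tgt[1])
  }
  st <- eval_shapes(shapes, mean_visc)
  loss <- sum((st$mean - tgt)^2)
  cfg <- model_config("combined", mean_visc_rel_water = mean_visc,
                      sigma_cell = shapes[1], sigma_spatial = shapes[2],
                      domain_size_nm = domain_size_nm, seed = seed)
  structure(list(config = cfg, loss = loss,
                 achieved = stats::setNames(st$mean,
                     c("mu_log", "sigma_track", "sigma_cell")),
                 targets = tgt, replicate_spread = st$spread,
                 converged = loss <= opts$tol, n_eval = n_eval),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result", if (!x$converged) "(NOT converged)", "\n")
  print(x$config)
  cat(sprintf("  loss %.3g over %d evaluations\n", x$loss, x$n_eval))
  lab <- c("mu_log", "sigma_track", "sigma_cell")
  for (i in 1:3)
    cat(sprintf("  %-12s target %.4f achieved %.4f (rep spread %.4f)\n",
                lab[i], x$targets[i], x$achieved[i],
                x$replicate_spread[i]))
  invisible(x)
}
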