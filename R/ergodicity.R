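#' Ensemble-averaged MSD (from each track's origin)
#'
#' The EA MSD at lag tau is the squared displacement relative to the
#' track's first tracked frame (its origin), averaged over all tracks still
#' alive at tau.  95% CIs come from a basic percentile bootstrap over
#' tracks with a sample size equal to the number of tracks.
#'
#' @param ts A `track_set`.
#' @param max_lag Largest lag in frames.
#' @param n_boot Bootstrap draws (0 disables the CI).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with `lag_ms`, `msd`, `ci_lo`, `ci_hi`, `n_contrib`.
#' @export
ensemble_msd <- function(ts, max_lag = 50, n_boot = 500, seed = 1) {
  validate_track_set(ts)
  if (n_tracks(ts) == 0L) stop("empty track_set")
  mat <- .origin_sq_matrix(ts, max_lag)
  ea <- colMeans(mat, na.rm = TRUE)
  n <- colSums(!is.na(mat))
  lo <- hi <- rep(NA_real_, ncol(mat))
  if (n_boot > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    nr <- nrow(mat)
    bs <- matrix(NA_real_, nrow = n_boot, ncol = ncol(mat))
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nr, nr, replace = TRUE)
      bs[b, ] <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    }
    lo <- apply(bs, 2, stats::quantile, 0.025, na.rm = TRUE, names = FALSE)
    hi <- apply(bs, 2, stats::quantile, 0.975, na.rm = TRUE, names = FALSE)
  }
  data.frame(lag_ms = seq_len(max_lag) * ts$frame_interval_ms,
             msd = ea, ci_lo = lo, ci_hi = hi, n_contrib = as.integer(n))
}

# squared from-origin displacement of every track at lags 1..max_lag
.origin_sq_matrix <- function(ts, max_lag) {
  ids <- as.character(ts$tracks$track_id)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = max_lag,
                dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    m <- ts$positions[[ids[i]]]
    kk <- min(max_lag, nrow(m) - 1L)
    if (kk >= 1L)
      mat[i, seq_len(kk)] <- (m[1L + seq_len(kk), 1] - m[1, 1])^2 +
                             (m[1L + seq_len(kk), 2] - m[1, 2])^2
  }
  mat
}

#' Percent difference between ensemble- and time-ensemble-averaged MSD
#'
#' percent_diff = (EA - TEA) * 100 / EA per lag; lags where EA is zero (or
#' undefined) are dropped with a warning.  Equal curves give 0 everywhere;
#' EA = 2 TEA gives 50%.
#'
#' @param ea data.frame with `lag_ms` and `msd` (EA curve).
#' @param tea data.frame with `lag_ms` and `msd` (TEA curve).
#' @return data.frame with `lag_ms` and `percent_diff` on the common lags.
#' @export
ergodicity_percent_difference <- function(ea, tea) {
  common <- intersect(ea$lag_ms, tea$lag_ms)
  if (!length(common)) stop("no common lags between EA and TEA curves")
  e <- ea$msd[match(common, ea$lag_ms)]
  t <- tea$msd[match(common, tea$lag_ms)]
  keep <- is.finite(e) & is.finite(t) & e != 0
  if (any(!keep))
    warning("dropping ", sum(!keep), " lag(s) with zero/undefined EA MSD")
  data.frame(lag_ms = common[keep],
             percent_diff = (e[keep] - t[keep]) * 100 / e[keep])
}

#' EA vs TEA MSD comparison for a track set
#'
#' Computes both MSD flavours on the same lags — the TEA curve is the
#' ensemble of nonoverlapping-window time averages, identical to
#' [ensemble_average_msd()] over [time_averaged_msd()] curves — together
#' with the per-lag percent difference and its bootstrap SE (EA and TEA are
#' recomputed from the same track resample in each draw, so the SE
#' propagates their correlation).
#'
#' @param ts A `track_set`.
#' @param max_lag Largest lag in frames.
#' @param n_boot Bootstrap draws.
#' @param seed RNG seed.
#' @return An `ergodicity_curves` object: data.frame with `lag_ms`,
#'   `ea_msd`, `ea_ci_lo`, `ea_ci_hi`, `tea_msd`, `percent_diff`,
#'   `percent_diff_se`, `pd_ci_lo`, `pd_ci_hi`, `n_contrib`.  When a
#'   bootstrap ran, the attribute `mean_pd` holds the lag-averaged percent
#'   difference and its 95% CI — the single statistic used to test
#'   "indistinguishable from zero".
#' @export
ergodicity_curves <- function(ts, max_lag = 50, n_boot = 500, seed = 1) {
  validate_track_set(ts)
  ea_mat <- .origin_sq_matrix(ts, max_lag)
  tea_mat <- .msd_matrix(ts, max_lag)
  ea <- colMeans(ea_mat, na.rm = TRUE)
  tea <- colMeans(tea_mat, na.rm = TRUE)
  n <- colSums(!is.na(ea_mat))
  pd <- (ea - tea) * 100 / ea
  nr <- nrow(ea_mat)
  se <- ea_lo <- ea_hi <- pd_lo <- pd_hi <- rep(NA_real_, max_lag)
  if (n_boot > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    pd_b <- matrix(NA_real_, nrow = n_boot, ncol = max_lag)
    ea_b <- matrix(NA_real_, nrow = n_boot, ncol = max_lag)
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nr, nr, replace = TRUE)
      eb <- colMeans(ea_mat[rows, , drop = FALSE], na.rm = TRUE)
      tb <- colMeans(tea_mat[rows, , drop = FALSE], na.rm = TRUE)
      ea_b[b, ] <- eb
      pd_b[b, ] <- (eb - tb) * 100 / eb
    }
    se <- apply(pd_b, 2, stats::sd, na.rm = TRUE)
    qf <- function(m, q) apply(m, 2, stats::quantile, q, na.rm = TRUE,
                               names = FALSE)
    ea_lo <- qf(ea_b, 0.025); ea_hi <- qf(ea_b, 0.975)
    pd_lo <- qf(pd_b, 0.025); pd_hi <- qf(pd_b, 0.975)
    # lag-averaged percent difference: one overall nonergodicity statistic
    # whose bootstrap CI tests "indistinguishable from 0" without the
    # multiplicity of per-lag intervals
    mean_draws <- rowMeans(pd_b, na.rm = TRUE)
    mean_pd <- c(mean = mean(pd, na.rm = TRUE),
                 ci_lo = stats::quantile(mean_draws, 0.025, names = FALSE),
                 ci_hi = stats::quantile(mean_draws, 0.975, names = FALSE))
  }
  out <- structure(
    data.frame(lag_ms = seq_len(max_lag) * ts$frame_interval_ms,
               ea_msd = ea, ea_ci_lo = ea_lo, ea_ci_hi = ea_hi,
               tea_msd = tea, percent_diff = pd,
               percent_diff_se = se,
               pd_ci_lo = pd_lo, pd_ci_hi = pd_hi,
               n_contrib = as.integer(n)),
    class = c("ergodicity_curves", "data.frame"))
  if (n_boot > 0) attr(out, "mean_pd") <- mean_pd
  out
}

#' Fit an exponential decay plus a constant
#'
#' Weighted nonlinear least squares of y = A exp(-B t) + C, weighted by
#' the inverse of the SE of each point when weights are supplied.
#' Initialisation: C0 = mean of the tail, A0 = mean of the head minus C0,
#' B0 from the lag where (y - C0) first halves.  Gauss-Newton via
#' `nls(algorithm = "port")` with a 1e-10 parameter tolerance, with a
#' Nelder-Mead/BFGS fallback; non-convergence is flagged, not fatal.
#'
#' @param lags Time values (ms).
#' @param y Response (e.g. percent difference).
#' @param weights Fit weights; give `1/se`.  Default equal weights.
#' @return An `exp_decay_fit`: list with `A`, `B` (1/ms), `C`,
#'   `residual_norm` (weighted), `converged`.
#' @export
fit_exp_decay <- function(lags, y, weights = NULL) {
  keep <- is.finite(lags) & is.finite(y) &
    (if (is.null(weights)) TRUE else is.finite(weights) & weights > 0)
  lags <- lags[keep]; y <- y[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(y) < 4L) stop("fit_exp_decay() needs >= 4 points")
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  n <- length(y)
  nh <- max(1L, floor(n / 5))
  C0 <- mean(y[(n - nh + 1L):n])
  A0 <- mean(y[seq_len(nh)]) - C0
  half <- which(abs(y - C0) <= abs(A0) / 2)
  t_half <- if (length(half)) lags[half[1]] else lags[ceiling(n / 2)]
  B0 <- log(2) / max(t_half - lags[1], diff(range(lags)) / n)
  if (abs(A0) < .Machine$double.eps^0.5) A0 <- sign(A0 + 1e-300) * 1e-6
  fit <- tryCatch(suppressWarnings({
    m <- stats::nls(y ~ A * exp(-B * t) + C,
                    data = list(y = y, t = lags),
                    start = list(A = A0, B = B0, C = C0),
                    weights = w^2,
                    algorithm = "port",
                    control = stats::nls.control(maxiter = 500,
                                                 tol = 1e-10,
                                                 warnOnly = TRUE))
    cf <- stats::coef(m)
    list(par = cf, converged = m$convInfo$isConv)
  }), error = function(e) NULL)
  obj <- function(par)
    sum((w * (y - (par[1] * exp(-par[2] * lags) + par[3])))^2)
  if (is.null(fit)) {
    o <- stats::optim(c(A0, B0, C0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    fit <- list(par = o$par, converged = o$convergence == 0)
  }
  par <- unname(fit$par)
  structure(list(A = par[1], B = par[2], C = par[3],
                 residual_norm = sqrt(obj(par)),
                 converged = isTRUE(fit$converged)),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "exp_decay_fit: y = %.4g * exp(-%.4g t) + %.4g  (residual %.3g%s)\n",
    x$A, x$B, x$C, x$residual_norm,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Calibrated viscosity-model parameters per spatial domain size
#'
#' Best-fit combined-model parameters (population mean viscosity relative
#' to water, cell-level and domain-level log-normal shapes) that reproduce
#' the experimental diffusivity mean and variance at each spatial domain
#' size.
#'
#' @return data.frame with `domain_size_nm`, `mean_visc_rel_water`,
#'   `sigma_cell`, `sigma_spatial`.
#' @export
domain_calibration_defaults <- function() {
  data.frame(domain_size_nm = c(100, 300, 600, 1000, 3000),
             mean_visc_rel_water = c(50, 39, 38, 40.5, 41.5),
             sigma_cell = c(0.375, 0.4, 0.4, 0.4, 0),
             sigma_spatial = c(1.1, 1.0, 0.9, 0.8, 0.775))
}

#' Scan nonergodicity against spatial-heterogeneity domain size
#'
#' For each domain size, runs `n_replicates` full doppelganger simulations
#' of the ledger under the combined model with that size's calibrated
#' shapes, computes each replicate's EA/TEA percent-difference curve, fits
#' the exponential decay, and averages the fitted parameters across
#' replicates.
#'
#' @param stats An `experiment_stats` ledger.
#' @param sizes Domain sizes (nm) to scan; defaults to the calibrated
#'   sizes of [domain_calibration_defaults()].
#' @param configs Optional data.frame like [domain_calibration_defaults()]
#'   supplying per-size parameters (required for sizes outside the
#'   defaults).
#' @param n_replicates Replicate simulations per size (default 50).
#' @param p [physical_params()].
#' @param max_lag Largest lag in frames for the MSD curves.
#' @param min_tracks Lags with fewer contributing tracks are excluded from
#'   the decay fit (tail noise guard).
#' @param n_boot Bootstrap draws for the per-replicate percent-difference
#'   SE used as fit weights.
#' @param seed Root seed; replicates use root + replicate-index
#'   substreams.
#' @return A list per size: `fits` (per-replicate data.frame of A, B, C),
#'   `mean_fit` (averaged parameters, as an `exp_decay_fit`), `curves`
#'   (list of percent-difference data.frames).
#' @export
domain_size_scan <- function(stats, sizes = NULL, configs = NULL,
                             n_replicates = 50, p = physical_params(),
                             max_lag = 50, min_tracks = 10, n_boot = 200,
                             seed = 1) {
  defaults <- domain_calibration_defaults()
  if (is.null(configs)) configs <- defaults
  if (is.null(sizes)) sizes <- configs$domain_size_nm
  missing_sz <- setdiff(sizes, configs$domain_size_nm)
  if (length(missing_sz))
    stop("no calibrated parameters for domain size(s): ",
         paste(missing_sz, collapse = ", "),
         " — supply them via `configs`")
  rep_seeds <- .substream_seeds(seed, length(sizes) * n_replicates)
  out <- vector("list", length(sizes))
  names(out) <- as.character(sizes)
  for (si in seq_along(sizes)) {
    row <- configs[match(sizes[si], configs$domain_size_nm), ]
    fits <- matrix(NA_real_, nrow = n_replicates, ncol = 3,
                   dimnames = list(NULL, c("A", "B", "C")))
    curves <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      cfg <- model_config("combined",
                          mean_visc_rel_water = row$mean_visc_rel_water,
                          sigma_cell = row$sigma_cell,
                          sigma_spatial = row$sigma_spatial,
                          domain_size_nm = sizes[si],
                          seed = rep_seeds[(si - 1L) * n_replicates + r])
      sim <- run_doppelganger(stats, cfg, p)
      ec <- ergodicity_curves(sim, max_lag = max_lag, n_boot = n_boot,
                              seed = cfg$seed)
      use <- ec$n_contrib >= min_tracks & is.finite(ec$percent_diff)
      fit <- fit_exp_decay(ec$lag_ms[use], ec$percent_diff[use],
                           weights = 1 / ec$percent_diff_se[use])
      fits[r, ] <- c(fit$A, fit$B, fit$C)
      curves[[r]] <- ec[, c("lag_ms", "percent_diff", "percent_diff_se",
                            "n_contrib")]
    }
    mf <- colMeans(fits)
    out[[si]] <- list(
      domain_size_nm = sizes[si],
      fits = as.data.frame(fits),
      mean_fit = structure(list(A = mf["A"], B = mf["B"], C = mf["C"],
                                residual_norm = NA_real_, converged = TRUE),
                           class = "exp_decay_fit"),
      curves = curves)
  }
  out
}
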