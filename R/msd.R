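#' Time-averaged MSD of one track with nonoverlapping windows
#'
#' For a lag of k frames the windows start at the first point and tile
#' forward without overlap, discarding any remainder: a track with points
#' x_1..x_7 at lag k = 3 has MSD_x = ((x_4 - x_1)^2 + (x_7 - x_4)^2) / 2.
#' Per-axis means are computed with this windowing and summed over x and y.
#' Lags with zero complete windows (k > n - 1) are absent from the curve.
#'
#' @param tr Either a `track_set` (with `track_id` naming one track) or an
#'   n x 2 position matrix.
#' @param max_lag Largest lag in frames to evaluate.
#' @param track_id Track to use when `tr` is a `track_set`.
#' @return An `msd_curve`: data.frame with columns `lag_ms`, `msd` (nm^2),
#'   `se` (nm^2; SD across windows / sqrt(n), NA for a single window) and
#'   `n_contrib` (number of windows), with attribute `frame_interval_ms`.
#' @export
time_averaged_msd <- function(tr, max_lag = 7, track_id = NULL) {
  dt <- 10
  if (inherits(tr, "track_set")) {
    if (is.null(track_id)) {
      if (n_tracks(tr) != 1L)
        stop("track_id required when the track_set holds several tracks")
      track_id <- tr$tracks$track_id[1]
    }
    dt <- tr$frame_interval_ms
    tr <- tr$positions[[as.character(track_id)]]
    if (is.null(tr)) stop("unknown track_id: ", track_id)
  } else if (!is.null(attr(tr, "frame_interval_ms"))) {
    dt <- attr(tr, "frame_interval_ms")
  }
  n <- nrow(tr)
  if (n < 2L) stop("time_averaged_msd() needs a track with >= 2 points")
  stopifnot(max_lag >= 1)
  lags <- seq_len(min(max_lag, n - 1L))
  msd <- se <- numeric(length(lags))
  m <- integer(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    idx <- seq.int(1L, n, by = k)        # window endpoints 1, 1+k, 1+2k, ...
    sq <- diff(tr[idx, 1])^2 + diff(tr[idx, 2])^2
    m[i] <- length(sq)
    msd[i] <- mean(sq)
    se[i] <- if (m[i] > 1L) stats::sd(sq) / sqrt(m[i]) else NA_real_
  }
  new_msd_curve(lags * dt, msd, se, m, dt)
}

new_msd_curve <- function(lag_ms, msd, se, n_contrib, frame_interval_ms) {
  structure(data.frame(lag_ms = lag_ms, msd = msd, se = se,
                       n_contrib = n_contrib),
            frame_interval_ms = frame_interval_ms,
            class = c("msd_curve", "data.frame"))
}

#' Ensemble average of MSD curves
#'
#' Per lag, the unweighted mean over all curves defined at that lag; the
#' standard error is the SD across contributing curves divided by
#' sqrt(n_contrib).  Curves defined on disjoint lags contribute each to
#' their own lags (error bars grow with lag as fewer tracks survive).
#'
#' @param curves List of `msd_curve` objects.
#' @return An `msd_curve` whose `n_contrib` counts contributing curves.
#' @export
ensemble_average_msd <- function(curves) {
  if (!length(curves)) stop("ensemble_average_msd() needs >= 1 curve")
  dt <- attr(curves[[1]], "frame_interval_ms")
  lag_all <- sort(unique(unlist(lapply(curves, function(cv) cv$lag_ms))))
  vals <- matrix(NA_real_, nrow = length(curves), ncol = length(lag_all))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    vals[i, match(cv$lag_ms, lag_all)] <- cv$msd
  }
  n <- colSums(!is.na(vals))
  mu <- colMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 2, stats::sd, na.rm = TRUE)
  se <- ifelse(n > 1L, sdv / sqrt(n), NA_real_)
  new_msd_curve(lag_all, mu, se, as.integer(n), dt)
}

#' Fit a power law MSD = A (tau/tau0)^alpha
#'
#' Ordinary least squares of ln(MSD) on ln(tau/tau0) over the first
#' `n_lags` available lags (about 70 ms at 10 ms framing).  `alpha` is the
#' slope; `A = exp(intercept)` is the MSD extrapolated to the reference lag
#' tau0; the apparent diffusivity is `d_app = A / (2 * n_dims * tau0)` with
#' n_dims = 2.
#'
#' @param curve An `msd_curve`.
#' @param n_lags Number of leading lags to fit (default 7).
#' @param tau0 Reference lag, ms (default 100).
#' @return A `power_law_fit`: list with `alpha`, `amplitude_A` (nm^2),
#'   `d_app` (nm^2/ms), `tau0`, `n_lags_fit`, `n_dims`, `lags_used`, and
#'   `ci95` (NULL until filled by [bootstrap_fit_ci()]).
#' @export
fit_power_law <- function(curve, n_lags = 7, tau0 = 100) {
  stopifnot(n_lags >= 2)
  use <- utils::head(which(is.finite(curve$msd)), n_lags)
  if (length(use) < 2L)
    stop("fit_power_law() needs >= 2 finite lags among the first ", n_lags)
  y <- curve$msd[use]
  if (any(y <= 0))
    stop("fit_power_law(): non-positive MSD among fitted lags")
  lx <- log(curve$lag_ms[use] / tau0)
  ly <- log(y)
  # closed-form OLS; the test suite checks this against lm() on log-log data
  mx <- mean(lx); my <- mean(ly)
  slope <- sum((lx - mx) * (ly - my)) / sum((lx - mx)^2)
  intercept <- my - slope * mx
  A <- exp(intercept)
  structure(list(alpha = slope, amplitude_A = A,
                 d_app = A / (2 * 2 * tau0), tau0 = tau0,
                 n_lags_fit = length(use), n_dims = 2L,
                 lags_used = curve$lag_ms[use], ci95 = NULL),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power_law_fit: alpha = %.3f, D_app(tau0 = %g ms) = %.4g nm^2/ms (%.4g um^2/s)\n",
    x$alpha, x$tau0, x$d_app, nm2ms_to_um2s(x$d_app)))
  if (!is.null(x$ci95)) {
    cat(sprintf("  95%% CI alpha [%.3f, %.3f], d_app [%.4g, %.4g]\n",
                x$ci95["alpha_lo"], x$ci95["alpha_hi"],
                x$ci95["d_app_lo"], x$ci95["d_app_hi"]))
  }
  invisible(x)
}

# Time-averaged MSD values of every track over the first n_lags lags, as a
# matrix (tracks x lags).  All filtered tracks (>= 10 points) define all of
# the first 7 lags, but shorter tracks yield NA columns.
.msd_matrix <- function(ts, n_lags = 7) {
  ids <- as.character(ts$tracks$track_id)
  out <- matrix(NA_real_, nrow = length(ids), ncol = n_lags,
                dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    m <- ts$positions[[ids[i]]]
    n <- nrow(m)
    if (n < 2L) next
    for (k in seq_len(min(n_lags, n - 1L))) {
      idx <- seq.int(1L, n, by = k)
      out[i, k] <- mean(diff(m[idx, 1])^2 + diff(m[idx, 2])^2)
    }
  }
  out
}

# OLS power-law fit for each row of an MSD matrix; returns data.frame of
# alpha, amplitude_A, d_app and a status string ("ok" or reason).
.fit_msd_matrix <- function(msd_mat, lag_ms, n_lags = 7, tau0 = 100) {
  k <- ncol(msd_mat)
  lx <- log(lag_ms / tau0)
  nr <- nrow(msd_mat)
  alpha <- A <- rep(NA_real_, nr)
  status <- rep("ok", nr)
  for (i in seq_len(nr)) {
    y <- msd_mat[i, ]
    use <- which(is.finite(y))
    if (length(use) < 2L) { status[i] <- "too_few_lags"; next }
    if (any(y[use] <= 0)) { status[i] <- "nonpositive_msd"; next }
    xx <- lx[use]; yy <- log(y[use])
    mx <- mean(xx); my <- mean(yy)
    sl <- sum((xx - mx) * (yy - my)) / sum((xx - mx)^2)
    alpha[i] <- sl
    A[i] <- exp(my - sl * mx)
  }
  data.frame(alpha = alpha, amplitude_A = A, d_app = A / (2 * 2 * tau0),
             status = status, stringsAsFactors = FALSE)
}

#' Power-law fits at track, cell or condition level
#'
#' Track-wise: the time-averaged MSD is calculated and fitted separately
#' for each trajectory.  Cell-wise / condition-wise: the per-track
#' time-averaged MSDs are ensemble-averaged over all tracks in each cell
#' (or over the whole set) before fitting.
#'
#' @param ts A `track_set` (already length-filtered).
#' @param level One of `"track"`, `"cell"`, `"condition"`.
#' @param n_lags,tau0 Passed to [fit_power_law()].
#' @return data.frame keyed by unit (`track_id`/`cell_id`/`condition`) with
#'   columns `alpha`, `amplitude_A`, `d_app` (nm^2/ms), `d_app_um2_s`,
#'   `n_tracks`, `status`; units whose fit failed carry NA estimates and a
#'   reason in `status`.
#' @export
fit_hierarchy <- function(ts, level = c("track", "cell", "condition"),
                          n_lags = 7, tau0 = 100) {
  level <- match.arg(level)
  validate_track_set(ts)
  lag_ms <- seq_len(n_lags) * ts$frame_interval_ms
  mat <- .msd_matrix(ts, n_lags)
  if (level == "track") {
    fits <- .fit_msd_matrix(mat, lag_ms, n_lags, tau0)
    out <- cbind(ts$tracks[, c("track_id", "cell_id", "session_id", "day_id")],
                 fits, n_tracks = 1L)
  } else {
    groups <- if (level == "cell") split(seq_len(nrow(mat)), ts$tracks$cell_id)
              else list(condition = seq_len(nrow(mat)))
    agg <- t(vapply(groups, function(rows)
      colMeans(mat[rows, , drop = FALSE], na.rm = TRUE), numeric(n_lags)))
    agg[!is.finite(agg)] <- NA_real_
    fits <- .fit_msd_matrix(agg, lag_ms, n_lags, tau0)
    out <- data.frame(unit = names(groups), fits,
                      n_tracks = lengths(groups), stringsAsFactors = FALSE)
    names(out)[1] <- if (level == "cell") "cell_id" else "condition"
    if (level == "cell") {
      idx <- match(out$cell_id, ts$cells$cell_id)
      out <- cbind(out[1], ts$cells[idx, c("session_id", "day_id")],
                   out[-1])
      rownames(out) <- NULL
    }
  }
  out$d_app_um2_s <- nm2ms_to_um2s(out$d_app)
  rownames(out) <- NULL
  out
}

#' Velocity autocorrelation of one track
#'
#' Velocities are single-frame displacement vectors divided by the frame
#' interval; VAC(tau) averages the dot products v(t) . v(t + tau) over
#' nonoverlapping t (t advancing by the lag), and VAC(0) is the mean
#' squared speed.  For pure diffusion VAC vanishes at all positive lags —
#' no negative peak, in contrast to viscoelastic subdiffusion.
#'
#' @param tr A `track_set` holding one track (or with `track_id` given), or
#'   an n x 2 position matrix.
#' @param max_lag Largest lag in frames (lag 0 is always included).
#' @param track_id Track to use when `tr` is a `track_set`.
#' @return A `vac_curve`: data.frame with `lag_ms`, `vac` (nm^2/ms^2), `se`
#'   and `n_contrib`.
#' @export
velocity_autocorrelation <- function(tr, max_lag = 7, track_id = NULL) {
  dt <- 10
  if (inherits(tr, "track_set")) {
    if (is.null(track_id)) {
      if (n_tracks(tr) != 1L)
        stop("track_id required when the track_set holds several tracks")
      track_id <- tr$tracks$track_id[1]
    }
    dt <- tr$frame_interval_ms
    tr <- tr$positions[[as.character(track_id)]]
  }
  n <- nrow(tr)
  if (n < 3L) stop("velocity_autocorrelation() needs >= 3 points")
  v <- diff(tr) / dt                    # (n-1) x 2 velocities
  nv <- nrow(v)
  lags <- 0:min(max_lag, nv - 1L)
  vac <- se <- numeric(length(lags))
  m <- integer(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    t0 <- if (k == 0L) seq_len(nv) else seq.int(1L, nv - k, by = k)
    dots <- rowSums(v[t0, , drop = FALSE] * v[t0 + k, , drop = FALSE])
    m[i] <- length(dots)
    vac[i] <- mean(dots)
    se[i] <- if (m[i] > 1L) stats::sd(dots) / sqrt(m[i]) else NA_real_
  }
  structure(data.frame(lag_ms = lags * dt, vac = vac, se = se,
                       n_contrib = m),
            frame_interval_ms = dt,
            class = c("vac_curve", "data.frame"))
}

#' Ensemble-averaged velocity autocorrelation across all tracks
#'
#' @param ts A `track_set`.
#' @param max_lag Largest lag in frames.
#' @return A `vac_curve` averaged per lag across tracks (same averaging
#'   order as the MSD: time first, then ensemble).
#' @export
ensemble_velocity_autocorrelation <- function(ts, max_lag = 7) {
  validate_track_set(ts)
  ids <- as.character(ts$tracks$track_id[ts$tracks$n_points >= 3L])
  if (!length(ids)) stop("no track with >= 3 points")
  curves <- lapply(ids, function(id) {
    m <- ts$positions[[id]]
    attr(m, "frame_interval_ms") <- ts$frame_interval_ms
    velocity_autocorrelation(m, max_lag = max_lag)
  })
  dt <- ts$frame_interval_ms
  lag_all <- sort(unique(unlist(lapply(curves, function(cv) cv$lag_ms))))
  vals <- matrix(NA_real_, nrow = length(curves), ncol = length(lag_all))
  for (i in seq_along(curves))
    vals[i, match(curves[[i]]$lag_ms, lag_all)] <- curves[[i]]$vac
  n <- colSums(!is.na(vals))
  mu <- colMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 2, stats::sd, na.rm = TRUE)
  structure(data.frame(lag_ms = lag_all, vac = mu,
                       se = ifelse(n > 1, sdv / sqrt(n), NA_real_),
                       n_contrib = as.integer(n)),
            frame_interval_ms = dt,
            class = c("vac_curve", "data.frame"))
}

#' Bootstrap confidence intervals for an ensemble power-law fit
#'
#' Basic percentile bootstrap with a sample size equal to the number of
#' tracks: tracks (their time-averaged MSD curves) are resampled with
#' replacement, the ensemble curve re-averaged and refitted each draw.
#'
#' @param curves List of per-track `msd_curve` objects, or a `track_set`
#'   (curves are computed with `n_lags` lags).
#' @param n_boot Number of bootstrap draws (>= 100).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param n_lags,tau0 Fit window, as in [fit_power_law()].
#' @return A `power_law_fit` for the full ensemble whose `ci95` element
#'   holds the percentile intervals (`alpha_lo`, `alpha_hi`, `d_app_lo`,
#'   `d_app_hi`).
#' @export
bootstrap_fit_ci <- function(curves, n_boot = 1000, seed = 1,
                             n_lags = 7, tau0 = 100) {
  stopifnot(n_boot >= 100)
  if (inherits(curves, "track_set")) {
    ts <- curves
    mat <- .msd_matrix(ts, n_lags)
    lag_ms <- seq_len(n_lags) * ts$frame_interval_ms
  } else {
    lag_ms <- seq_len(n_lags) * attr(curves[[1]], "frame_interval_ms")
    mat <- matrix(NA_real_, nrow = length(curves), ncol = n_lags)
    for (i in seq_along(curves)) {
      cv <- curves[[i]]
      sel <- match(cv$lag_ms, lag_ms)
      ok <- !is.na(sel)
      mat[i, sel[ok]] <- cv$msd[ok]
    }
  }
  ens <- colMeans(mat, na.rm = TRUE)
  ens[!is.finite(ens)] <- NA_real_
  point <- .fit_msd_matrix(rbind(ens), lag_ms, n_lags, tau0)
  if (point$status != "ok") stop("ensemble curve not fittable: ", point$status)
  nr <- nrow(mat)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  alpha_b <- d_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nr, nr, replace = TRUE)
    eb <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    eb[!is.finite(eb)] <- NA_real_
    fb <- .fit_msd_matrix(rbind(eb), lag_ms, n_lags, tau0)
    alpha_b[b] <- fb$alpha
    d_b[b] <- fb$d_app
  }
  q <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE,
                                   names = FALSE)
  qa <- q(alpha_b); qd <- q(d_b)
  structure(list(alpha = point$alpha, amplitude_A = point$amplitude_A,
                 d_app = point$d_app, tau0 = tau0,
                 n_lags_fit = sum(is.finite(ens[seq_len(n_lags)])),
                 n_dims = 2L, lags_used = lag_ms,
                 ci95 = c(alpha_lo = qa[1], alpha_hi = qa[2],
                          d_app_lo = qd[1], d_app_hi = qd[2]),
                 n_boot = n_boot, seed = seed),
            class = "power_law_fit")
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
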