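#' Configuration of a viscosity-heterogeneity model
#'
#' Four models of cytoplasmic viscosity are supported:
#' \describe{
#'   \item{uniform}{one viscosity for every cell (the population mean).}
#'   \item{spatial}{within each cell, a grid of square domains of side
#'     `domain_size_nm` each drawn log-normally about the population mean
#'     with shape `sigma_spatial`.}
#'   \item{cellular}{one viscosity per cell drawn log-normally about the
#'     population mean with shape `sigma_cell`.}
#'   \item{combined}{cell means drawn with `sigma_cell`, then domains drawn
#'     with `sigma_spatial` about each cell's mean.}
#' }
#' Draws follow eta = mu * exp(shape * z) with z standard normal (so `mu`
#' is the median of the resulting log-normal), and no viscosity may fall
#' below that of water: draws are clipped at the floor.
#'
#' @param model One of `"uniform"`, `"spatial"`, `"cellular"`, `"combined"`.
#' @param mean_visc_rel_water Population viscosity as a multiple of the
#'   viscosity of water at the simulation temperature (default 40).
#' @param sigma_cell Log-normal shape of the cell-to-cell spread
#'   (sigma_eta,c / <eta>, default 0.45).
#' @param sigma_spatial Log-normal shape of the domain-to-domain spread
#'   within a cell (sigma_eta,s / <eta_c>, default 0.85).
#' @param domain_size_nm Side length Lambda of the square spatial domains,
#'   nm (default 1000).
#' @param visc_floor Minimum viscosity, pN ms/nm^2; `NULL` means the
#'   viscosity of water at the simulation temperature.
#' @param seed RNG seed for the whole simulation run.
#' @return An object of class `model_config`.
#' @export
model_config <- function(model = c("uniform", "spatial", "cellular",
                                   "combined"),
                         mean_visc_rel_water = 40,
                         sigma_cell = 0.45, sigma_spatial = 0.85,
                         domain_size_nm = 1000, visc_floor = NULL,
                         seed = 1) {
  model <- match.arg(model)
  stopifnot(mean_visc_rel_water > 0, sigma_cell >= 0, sigma_spatial >= 0,
            domain_size_nm > 0)
  structure(list(model = model, mean_visc_rel_water = mean_visc_rel_water,
                 sigma_cell = sigma_cell, sigma_spatial = sigma_spatial,
                 domain_size_nm = domain_size_nm, visc_floor = visc_floor,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "model_config: %s | <eta> = %g eta_w, sigma_cell = %g, sigma_spatial = %g, Lambda = %g nm, seed = %d\n",
    x$model, x$mean_visc_rel_water, x$sigma_cell, x$sigma_spatial,
    x$domain_size_nm, x$seed))
  invisible(x)
}

#' Draw clipped log-normal viscosities
#'
#' eta_i = mu * exp(shape * z_i) with z_i standard normal; values below
#' `floor` are clipped to `floor` (viscosities below that of water are not
#' allowed).  Uses the current RNG state — seed outside.
#'
#' @param mu Median viscosity of the distribution, pN ms/nm^2.
#' @param shape Log-normal shape parameter (>= 0); 0 returns `mu` exactly.
#' @param n Number of draws.
#' @param floor Minimum admissible viscosity.
#' @return Numeric vector of `n` viscosities.
#' @export
sample_lognormal_viscosity <- function(mu, shape, n, floor = 0) {
  stopifnot(mu >= floor, shape >= 0, n >= 0)
  if (n == 0L) return(numeric(0))
  eta <- mu * exp(shape * stats::rnorm(n))
  pmax(eta, floor)
}

#' Build the viscosity landscape of one cell
#'
#' Spatial grids cover the rectangle [0, L] x [0, W] with square domains of
#' side Lambda: a 3-across arrangement for the default W = 3 um at
#' Lambda = 1 um, with an extra narrower column (and/or row, for Lambda not
#' dividing W) of remainder domains at the high-coordinate edge when the
#' cell dimension is not an integer multiple of Lambda.
#'
#' @param cell One row of a `track_set` cells table (needs `length_nm`,
#'   `width_nm`).
#' @param cfg A [model_config()].
#' @param p A [physical_params()] (sets the water-viscosity floor).
#' @param cell_mean Optional pre-drawn cell mean viscosity (pN ms/nm^2);
#'   when NULL the cell mean is derived from `cfg` (drawn for cellular /
#'   combined models, the population mean otherwise).
#' @return An object of class `viscosity_field`: list with `length_nm`,
#'   `width_nm`, `mode` ("single" or "grid"), `cell_mean_viscosity`,
#'   `x_breaks`, `y_breaks` and `values` (matrix, rows = y domains,
#'   columns = x domains) or a single value.
#' @export
build_viscosity_field <- function(cell, cfg, p = physical_params(),
                                  cell_mean = NULL) {
  L <- as.numeric(cell$length_nm); W <- as.numeric(cell$width_nm)
  stopifnot(is.finite(L), is.finite(W), L > 0, W > 0)
  floor_eta <- if (is.null(cfg$visc_floor)) water_viscosity(p$temperature_K)
               else cfg$visc_floor
  pop_mean <- cfg$mean_visc_rel_water * water_viscosity(p$temperature_K)
  if (is.null(cell_mean)) {
    cell_mean <- if (cfg$model %in% c("cellular", "combined"))
      sample_lognormal_viscosity(pop_mean, cfg$sigma_cell, 1L, floor_eta)
    else pop_mean
  }
  spatial <- cfg$model %in% c("spatial", "combined")
  if (!spatial) {
    return(structure(list(length_nm = L, width_nm = W, mode = "single",
                          cell_mean_viscosity = cell_mean,
                          values = cell_mean,
                          x_breaks = c(0, L), y_breaks = c(0, W)),
                     class = "viscosity_field"))
  }
  Lam <- cfg$domain_size_nm
  if (Lam > min(L, W)) {
    warning("domain size exceeds the cell's smaller dimension; ",
            "using a single-domain grid")
    xb <- c(0, L); yb <- c(0, W)
  } else {
    xb <- .domain_breaks(L, Lam)
    yb <- .domain_breaks(W, Lam)
  }
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  # spatial model: domains about the cell's mean (= population mean when
  # there is no cellular component)
  vals <- sample_lognormal_viscosity(cell_mean, cfg$sigma_spatial,
                                     nx * ny, floor_eta)
  structure(list(length_nm = L, width_nm = W, mode = "grid",
                 cell_mean_viscosity = cell_mean,
                 values = matrix(vals, nrow = ny, ncol = nx),
                 x_breaks = xb, y_breaks = yb),
            class = "viscosity_field")
}

# breaks 0, Lam, 2 Lam, ..., plus a final narrower remainder domain when
# len is not an integer multiple of Lam
.domain_breaks <- function(len, Lam) {
  n_full <- floor(len / Lam + 1e-9)
  b <- seq(0, n_full * Lam, by = Lam)
  if (len - b[length(b)] > 1e-9 * max(len, 1)) b <- c(b, len)
  else b[length(b)] <- len
  b
}

#' Viscosity at a position
#'
#' Half-open domain convention: the domain index along an axis is
#' floor(coordinate / Lambda) clamped into the grid, so a point exactly on
#' an interior boundary belongs to the higher-index domain; the outer cell
#' edge belongs to the last domain.
#'
#' @param field A `viscosity_field`.
#' @param x,y Position, nm; must lie inside [0, L] x [0, W].
#' @return Viscosity at (x, y), pN ms/nm^2.
#' @export
viscosity_at <- function(field, x, y) {
  if (any(x < 0 | x > field$length_nm | y < 0 | y > field$width_nm))
    stop("viscosity_at(): position outside the cell box")
  if (field$mode == "single") return(rep(field$values, length(x))[seq_along(x)])
  ix <- pmin(findInterval(x, field$x_breaks), length(field$x_breaks) - 1L)
  iy <- pmin(findInterval(y, field$y_breaks), length(field$y_breaks) - 1L)
  field$values[cbind(iy, ix)]
}
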