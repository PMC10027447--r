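#' Physical parameters for Brownian-dynamics simulations
#'
#' Bundles the physical constants used throughout the simulator.  Canonical
#' units are nm, ms, pN and K, so that viscosities come out in pN ms/nm^2,
#' drag coefficients in pN ms/nm and diffusivities in nm^2/ms
#' (1 nm^2/ms = 1e-3 um^2/s).
#'
#' @param k_B Boltzmann constant, pN nm/K.
#' @param temperature_K Absolute temperature, K.  Default 303.15 K (30 C),
#'   the growth and imaging temperature of the experiments being emulated.
#' @param radius_nm Particle radius, nm.  Default 20 nm (a 40 nm-diameter
#'   multimeric nanoparticle).
#' @param dt_ms Simulation timestep, ms.  Must equal the frame interval of
#'   the ledger being replicated; default 10 ms (100 Hz imaging).
#' @return An object of class `physical_params`.
#' @export
physical_params <- function(k_B = 0.0138, temperature_K = 303.15,
                            radius_nm = 20, dt_ms = 10) {
  stopifnot(k_B > 0, temperature_K > 0, radius_nm > 0, dt_ms > 0)
  structure(list(k_B = k_B, temperature_K = temperature_K,
                 radius_nm = radius_nm, dt_ms = dt_ms),
            class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Physical parameters:\n")
  cat(sprintf("  k_B        %g pN nm/K\n", x$k_B))
  cat(sprintf("  T          %g K\n", x$temperature_K))
  cat(sprintf("  R          %g nm\n", x$radius_nm))
  cat(sprintf("  dt         %g ms\n", x$dt_ms))
  cat(sprintf("  k_B T      %.4g pN nm\n", thermal_energy(x)))
  invisible(x)
}

#' Thermal energy k_B * T
#'
#' @param p A [physical_params()] object.
#' @return Thermal energy in pN nm.
#' @export
thermal_energy <- function(p) p$k_B * p$temperature_K

#' Dynamic viscosity of water
#'
#' Empirical temperature dependence of the dynamic viscosity of water,
#' eta_w(T) = 2.414e-8 * 10^(247.8 / (T - 140)) pN ms/nm^2.  At 30 C this
#' evaluates to about 8e-7 pN ms/nm^2 (0.8 mPa s).
#'
#' @param temperature_K Absolute temperature in K; must exceed 150 K.
#' @return Viscosity in pN ms/nm^2.
#' @export
water_viscosity <- function(temperature_K) {
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 150))
    stop("water_viscosity() requires temperature_K > 150 K")
  2.414e-8 * 10^(247.8 / (temperature_K - 140))
}

#' Stokes drag coefficient
#'
#' gamma = 6 * pi * eta * R for a sphere of radius R in a medium of
#' viscosity eta.
#'
#' @param p A [physical_params()] object (supplies R).
#' @param eta Viscosity, pN ms/nm^2.
#' @return Drag coefficient in pN ms/nm.
#' @export
drag_coefficient <- function(p, eta) {
  stopifnot(all(eta > 0))
  6 * pi * eta * p$radius_nm
}

#' Stokes-Einstein diffusivity
#'
#' D = k_B * T / (6 * pi * eta * R).  With the default parameters and a
#' cytoplasmic viscosity 40 times that of water at 30 C, D is about
#' 350 nm^2/ms (0.35 um^2/s).
#'
#' @param p A [physical_params()] object.
#' @param eta Viscosity (scalar or vector), pN ms/nm^2.
#' @return Diffusivity in nm^2/ms.
#' @export
stokes_einstein_diffusivity <- function(p, eta) {
  thermal_energy(p) / drag_coefficient(p, eta)
}

#' Per-axis Brownian step standard deviation
#'
#' xi = sqrt(2 * D * dt) with D = k_B T / gamma; each Cartesian component of
#' a displacement over one timestep is drawn from N(0, xi^2).  The mean 2D
#' (Euclidean) step length is then xi * sqrt(pi / 2).
#'
#' @param p A [physical_params()] object.
#' @param eta Viscosity, pN ms/nm^2.
#' @return Step standard deviation in nm.
#' @export
brownian_step_sd <- function(p, eta) {
  sqrt(2 * stokes_einstein_diffusivity(p, eta) * p$dt_ms)
}

# nm^2/ms -> um^2/s conversion factor (1 nm^2/ms = 1e-6 um^2 * 1e3 /s)
.NM2_MS_TO_UM2_S <- 1e-3

#' Convert diffusivities between nm^2/ms and um^2/s
#'
#' @param d Diffusivity values.
#' @return Converted values.
#' @export
nm2ms_to_um2s <- function(d) d * .NM2_MS_TO_UM2_S

#' @rdname nm2ms_to_um2s
#' @export
um2s_to_nm2ms <- function(d) d / .NM2_MS_TO_UM2_S
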