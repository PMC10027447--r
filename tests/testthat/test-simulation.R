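p0 <- physical_params()

test_that("water viscosity follows the empirical temperature formula", {
  expect_equal(signif(water_viscosity(303.15), 1), 8e-7)
  expect_equal(water_viscosity(293.15), 2.414e-8 * 10^(247.8 / 153.15))
  expect_equal(signif(water_viscosity(293.15), 3), 1.00e-6)
  temps <- seq(273, 373, by = 5)
  expect_true(all(diff(water_viscosity(temps)) < 0))
  expect_error(water_viscosity(150), "150 K")
})

test_that("Stokes-Einstein layer reproduces the derived constants", {
  eta <- 40 * water_viscosity(p0$temperature_K)
  expect_equal(signif(thermal_energy(p0), 3), 4.18)
  expect_equal(signif(drag_coefficient(p0, eta), 2), 0.012)
  expect_equal(signif(stokes_einstein_diffusivity(p0, eta), 2), 350)
  # D is inversely proportional to viscosity
  expect_equal(stokes_einstein_diffusivity(p0, 2 * eta),
               stokes_einstein_diffusivity(p0, eta) / 2)
  # at fixed viscosity, D scales with absolute temperature
  p20 <- physical_params(temperature_K = 293.15)
  expect_equal(stokes_einstein_diffusivity(p20, eta) /
                 stokes_einstein_diffusivity(p0, eta),
               293.15 / 303.15)
})

test_that("log-normal viscosity sampling: degenerate, median, and floor", {
  floor_eta <- water_viscosity(303.15)
  mu <- 40 * floor_eta
  set.seed(1)
  expect_equal(sample_lognormal_viscosity(mu, 0, 5, floor_eta),
               rep(mu, 5))
  draws <- sample_lognormal_viscosity(mu, 0.45, 1e5, floor_eta)
  expect_true(all(draws >= floor_eta))
  # mu is the median of the log-normal; clipping at 1/40 of the median is
  # a ~16 sigma event, so the clipped fraction is numerically zero
  expect_equal(median(draws), mu, tolerance = 0.01)
  expect_equal(mean(draws == floor_eta),
               pnorm(log(1 / 40) / 0.45), tolerance = 1e-4)
  # larger shape at play: clipped fraction matches the normal CDF
  draws2 <- sample_lognormal_viscosity(4 * floor_eta, 1.5, 2e5, floor_eta)
  expect_equal(mean(draws2 == floor_eta), pnorm(log(1 / 4) / 1.5),
               tolerance = 0.01)
})

test_that("viscosity fields: geometry of the domain grid", {
  cfg <- model_config("spatial", sigma_spatial = 0.85)
  set.seed(2)
  f <- build_viscosity_field(
    data.frame(length_nm = 10000, width_nm = 3000), cfg, p0)
  expect_equal(dim(f$values), c(3, 10))
  expect_equal(f$x_breaks, seq(0, 10000, by = 1000))
  expect_equal(f$y_breaks, seq(0, 3000, by = 1000))
  # a 10.4 um cell gets a narrower remainder column at the high-x end
  f2 <- build_viscosity_field(
    data.frame(length_nm = 10400, width_nm = 3000), cfg, p0)
  expect_equal(dim(f2$values), c(3, 11))
  expect_equal(diff(f2$x_breaks)[11], 400)
  # width not divisible by Lambda: remainder row along y as well
  cfg700 <- model_config("spatial", domain_size_nm = 700)
  f3 <- build_viscosity_field(
    data.frame(length_nm = 6000, width_nm = 3000), cfg700, p0)
  expect_equal(dim(f3$values), c(5, 9))
  expect_equal(diff(f3$y_breaks)[5], 200)
  expect_equal(diff(f3$x_breaks)[9], 400)
  # Lambda larger than the cell: single domain with warning
  cfg_big <- model_config("spatial", domain_size_nm = 5000)
  expect_warning(
    fbig <- build_viscosity_field(
      data.frame(length_nm = 10000, width_nm = 3000), cfg_big, p0),
    "single-domain")
  expect_equal(dim(fbig$values), c(1, 1))
})

test_that("zero shape parameters reduce every model to the uniform field", {
  pop <- 40 * water_viscosity(p0$temperature_K)
  for (mod in c("spatial", "cellular", "combined")) {
    cfg <- model_config(mod, sigma_cell = 0, sigma_spatial = 0)
    set.seed(3)
    f <- build_viscosity_field(
      data.frame(length_nm = 9000, width_nm = 3000), cfg, p0)
    expect_true(all(abs(f$values - pop) < 1e-12 * pop), info = mod)
  }
})

test_that("viscosity_at uses the half-open domain convention", {
  cfg <- model_config("spatial")
  set.seed(4)
  f <- build_viscosity_field(
    data.frame(length_nm = 10000, width_nm = 3000), cfg, p0)
  expect_equal(viscosity_at(f, 1500, 500), f$values[1, 2])
  # exact boundary x = Lambda belongs to the next domain
  expect_equal(viscosity_at(f, 1000, 0), f$values[1, 2])
  # outer edges clamp into the last domain
  expect_equal(viscosity_at(f, 10000, 3000), f$values[3, 10])
  expect_error(viscosity_at(f, -1, 0), "outside")
  uni <- build_viscosity_field(
    data.frame(length_nm = 10000, width_nm = 3000),
    model_config("uniform"), p0)
  expect_equal(viscosity_at(uni, 123, 456), uni$values)
})

test_that("reflection maps proposals as the bounce oracle does", {
  expect_equal(reflect_into_box(-50, 10000), 50)
  expect_equal(reflect_into_box(3100, 3000), 2900)
  expect_equal(reflect_into_box(-3100, 3000), 2900)
  set.seed(6)
  v <- runif(500, -4e4, 4e4)
  expect_equal(reflect_into_box(v, 3000), oracle_reflect(v, 3000))
})

test_that("one-step displacement variance matches the Brownian increment law", {
  field <- build_viscosity_field(
    data.frame(length_nm = 1e7, width_nm = 1e7),
    model_config("uniform"), p0)
  D <- stokes_einstein_diffusivity(p0, 40 * water_viscosity(303.15))
  set.seed(9)
  steps <- t(vapply(1:10000, function(i) {
    m <- simulate_track(field, 1, p0, start = c(5e6, 5e6))
    m[2, ] - m[1, ]
  }, numeric(2)))
  expect_equal(var(steps[, 1]), 2 * D * p0$dt_ms, tolerance = 0.05)
  expect_equal(var(steps[, 2]), 2 * D * p0$dt_ms, tolerance = 0.05)
  expect_equal(mean(steps), 0, tolerance = 3 * sqrt(2 * D * 10 / 2e4))
})

test_that("simulated positions never leave the box, even for long runs", {
  cfg <- model_config("combined", sigma_spatial = 1.5, sigma_cell = 0.5,
                      domain_size_nm = 500, seed = 1)
  set.seed(13)
  f <- build_viscosity_field(
    data.frame(length_nm = 7000, width_nm = 3000), cfg, p0)
  m <- simulate_track(f, 2000, p0)
  expect_true(all(m[, 1] >= 0 & m[, 1] <= 7000))
  expect_true(all(m[, 2] >= 0 & m[, 2] <= 3000))
  # uniform fast-path too
  uf <- build_viscosity_field(
    data.frame(length_nm = 7000, width_nm = 3000),
    model_config("uniform", mean_visc_rel_water = 2), p0)
  mu <- simulate_track(uf, 2000, p0)
  expect_true(all(mu[, 1] >= 0 & mu[, 1] <= 7000))
  expect_true(all(mu[, 2] >= 0 & mu[, 2] <= 3000))
})

test_that("doppelganger runs replicate the ledger exactly and deterministically", {
  stats <- small_ledger(n_cells = 10, seed = 21)
  for (mod in c("uniform", "combined")) {
    sim <- run_doppelganger(stats, model_config(mod, seed = 5), p0)
    expect_identical(extract_experiment_stats(sim), stats, info = mod)
  }
  a <- run_doppelganger(stats, model_config("combined", seed = 8), p0)
  b <- run_doppelganger(stats, model_config("combined", seed = 8), p0)
  expect_identical(a$positions, b$positions)
  c2 <- run_doppelganger(stats, model_config("combined", seed = 9), p0)
  expect_false(identical(a$positions, c2$positions))
  # timestep must match the ledger framing
  expect_error(run_doppelganger(stats, model_config("uniform", seed = 1),
                                physical_params(dt_ms = 5)),
               "frame interval")
})

test_that("degenerate heterogeneity models reproduce uniform-model MSD statistics", {
  stats <- small_ledger(n_cells = 25, seed = 31)
  uni <- run_doppelganger(stats, model_config("uniform", seed = 2), p0)
  deg <- run_doppelganger(stats, model_config("combined", sigma_cell = 0,
                                              sigma_spatial = 0, seed = 4),
                          p0)
  fu <- bootstrap_fit_ci(uni, n_boot = 200, seed = 1)
  fd <- bootstrap_fit_ci(deg, n_boot = 200, seed = 1)
  # same generating law: each fit lies inside the other's bootstrap CI
  expect_true(fd$d_app >= fu$ci95["d_app_lo"] &&
                fd$d_app <= fu$ci95["d_app_hi"])
  expect_true(fu$alpha >= fd$ci95["alpha_lo"] - 0.05 &&
                fu$alpha <= fd$ci95["alpha_hi"] + 0.05)
})

test_that("spread parameters act on their own level of the hierarchy", {
  stats <- small_ledger(n_cells = 30, seed = 41)
  sd_by <- function(cfg) {
    sim <- run_doppelganger(stats, cfg, p0)
    fits <- fit_hierarchy(sim, "track")
    ok <- fits$status == "ok"
    tg <- calibration_targets(log10(fits$d_app[ok]), fits$cell_id[ok])
    c(track = tg$sigma_track, cell = tg$sigma_cell)
  }
  base <- sd_by(model_config("combined", sigma_cell = 0.1,
                             sigma_spatial = 0.2, seed = 3))
  more_sp <- sd_by(model_config("combined", sigma_cell = 0.1,
                                sigma_spatial = 1.2, seed = 3))
  more_ce <- sd_by(model_config("combined", sigma_cell = 0.8,
                                sigma_spatial = 0.2, seed = 3))
  expect_gt(more_sp["track"], base["track"])
  expect_gt(more_ce["cell"], base["cell"])
})
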