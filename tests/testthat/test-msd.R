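test_that("nonoverlapping windowing matches the worked 7-point example", {
  set.seed(10)
  m <- random_walk(7)
  curve <- time_averaged_msd(m, max_lag = 6)
  expected_x <- ((m[4, 1] - m[1, 1])^2 + (m[7, 1] - m[4, 1])^2) / 2
  expected_y <- ((m[4, 2] - m[1, 2])^2 + (m[7, 2] - m[4, 2])^2) / 2
  expect_equal(curve$msd[curve$lag_ms == 30], expected_x + expected_y)
  expect_equal(curve$n_contrib[curve$lag_ms == 30], 2L)
})

test_that("deterministic motion gives an exact quadratic MSD", {
  n <- 41
  m <- cbind(10 * (0:(n - 1)), rep(0, n))
  curve <- time_averaged_msd(m, max_lag = 40)
  expect_equal(curve$msd, (10 * seq_len(40))^2)
  expect_equal(curve$lag_ms, 10 * seq_len(40))
})

test_that("windowing agrees with the brute-force enumerator on small tracks", {
  set.seed(99)
  for (n in c(2, 3, 7, 10, 23, 50, 100)) {
    m <- random_walk(n)
    curve <- time_averaged_msd(m, max_lag = n - 1)
    for (k in seq_len(n - 1)) {
      expect_equal(curve$msd[curve$lag_ms == k * 10], oracle_msd(m, k),
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("lags beyond the track span are absent, not zero", {
  m <- random_walk(5)
  curve <- time_averaged_msd(m, max_lag = 50)
  expect_equal(nrow(curve), 4L)
  expect_true(all(curve$lag_ms <= 40))
})

test_that("ensemble averaging handles identical and disjoint curves", {
  set.seed(4)
  c1 <- time_averaged_msd(random_walk(30), max_lag = 7)
  ens <- ensemble_average_msd(list(c1, c1))
  expect_equal(ens$msd, c1$msd)
  expect_equal(ens$se, rep(0, nrow(c1)))
  # disjoint lags: union, each lag from its sole contributor
  a <- c1[1:3, ]; attr(a, "frame_interval_ms") <- 10
  b <- c1[5:7, ]; attr(b, "frame_interval_ms") <- 10
  u <- ensemble_average_msd(list(a, b))
  expect_equal(u$lag_ms, c1$lag_ms[c(1:3, 5:7)])
  expect_equal(u$msd, c1$msd[c(1:3, 5:7)])
  expect_equal(u$n_contrib, rep(1L, 6))
  expect_error(ensemble_average_msd(list()), "curve")
})

test_that("simulated diffusion matches 4 D tau within ensemble error", {
  p <- physical_params()
  eta <- 40 * water_viscosity(p$temperature_K)
  D <- stokes_einstein_diffusivity(p, eta)
  field <- build_viscosity_field(
    data.frame(length_nm = 1e6, width_nm = 1e6),
    model_config("uniform"), p)
  set.seed(21)
  curves <- lapply(1:100, function(i) {
    m <- simulate_track(field, 200, p)
    time_averaged_msd(m, max_lag = 7)
  })
  ens <- ensemble_average_msd(curves)
  expect_true(all(abs(ens$msd - 4 * D * ens$lag_ms) < 3 * ens$se))
})

test_that("power-law fitting recovers exact power laws", {
  tau <- seq(10, 70, by = 10)
  lin <- new_curve <- structure(
    data.frame(lag_ms = tau, msd = 1400 * tau, se = NA, n_contrib = 1L),
    frame_interval_ms = 10, class = c("msd_curve", "data.frame"))
  fit <- fit_power_law(lin)
  expect_equal(fit$alpha, 1)
  expect_equal(fit$amplitude_A, 140000)
  expect_equal(fit$d_app, 350)
  sub <- structure(
    data.frame(lag_ms = tau, msd = 5000 * sqrt(tau), se = NA,
               n_contrib = 1L),
    frame_interval_ms = 10, class = c("msd_curve", "data.frame"))
  expect_equal(fit_power_law(sub)$alpha, 0.5)
})

test_that("d_app of an exact power law is invariant to which lags are present", {
  tau_full <- seq(10, 70, by = 10)
  mk <- function(tau) structure(
    data.frame(lag_ms = tau, msd = 900 * (tau / 100)^0.8, se = NA,
               n_contrib = 1L),
    frame_interval_ms = 10, class = c("msd_curve", "data.frame"))
  ref <- fit_power_law(mk(tau_full))
  for (keep in list(c(1, 4), c(2, 3, 7), c(1, 2, 3))) {
    fit <- fit_power_law(mk(tau_full[keep]))
    expect_equal(fit$d_app, ref$d_app)
    expect_equal(fit$alpha, ref$alpha)
  }
})

test_that("noisy curves reproduce an independent log-log lm() fit", {
  set.seed(8)
  for (i in 1:5) {
    m <- random_walk(60)
    curve <- time_averaged_msd(m, max_lag = 7)
    fit <- fit_power_law(curve)
    lmfit <- lm(log(msd) ~ log(lag_ms / 100), data = curve)
    expect_equal(fit$alpha, unname(coef(lmfit)[2]))
    expect_equal(fit$amplitude_A, exp(unname(coef(lmfit)[1])))
  }
})

test_that("non-positive MSD among fitted lags is a fit error", {
  bad <- structure(
    data.frame(lag_ms = c(10, 20, 30), msd = c(5, 0, 4), se = NA,
               n_contrib = 1L),
    frame_interval_ms = 10, class = c("msd_curve", "data.frame"))
  expect_error(fit_power_law(bad), "non-positive")
})

test_that("hierarchy fits: single-track cell equals its track fit; ordering is monotone", {
  set.seed(12)
  ts1 <- make_ts(list(random_walk(30)))
  tr <- fit_hierarchy(ts1, "track")
  ce <- fit_hierarchy(ts1, "cell")
  co <- fit_hierarchy(ts1, "condition")
  expect_equal(tr$d_app, ce$d_app)
  expect_equal(tr$alpha, co$alpha)
  # two cells with well-separated diffusivities keep their ordering
  p <- physical_params()
  slow <- build_viscosity_field(
    data.frame(length_nm = 1e4, width_nm = 3e3),
    model_config("uniform", mean_visc_rel_water = 400), p)
  fast <- build_viscosity_field(
    data.frame(length_nm = 1e4, width_nm = 3e3),
    model_config("uniform", mean_visc_rel_water = 4), p)
  mk <- function(field, n) lapply(seq_len(n), function(i)
    simulate_track(field, 50, p))
  ts2 <- make_ts(c(mk(slow, 5), mk(fast, 5)),
                 cell_ids = rep(c("slow", "fast"), each = 5))
  cf <- fit_hierarchy(ts2, "cell")
  expect_gt(cf$d_app[cf$cell_id == "fast"], cf$d_app[cf$cell_id == "slow"])
})

test_that("velocity autocorrelation: constant velocity and diffusive limits", {
  n <- 31
  m <- cbind(3 * (0:(n - 1)) * 10, 4 * (0:(n - 1)) * 10)  # |v| = 5 nm/ms
  vac <- velocity_autocorrelation(m, max_lag = 7)
  expect_equal(vac$vac, rep(25, 8))
  # diffusion: VAC(0) = 4 D / dt, VAC(k > 0) ~ 0
  p <- physical_params()
  D <- stokes_einstein_diffusivity(p, 40 * water_viscosity(p$temperature_K))
  field <- build_viscosity_field(
    data.frame(length_nm = 1e6, width_nm = 1e6),
    model_config("uniform"), p)
  set.seed(5)
  ts <- make_ts(lapply(1:60, function(i) simulate_track(field, 100, p)))
  evac <- ensemble_velocity_autocorrelation(ts, max_lag = 5)
  expect_equal(evac$vac[1], 4 * D / p$dt_ms,
               tolerance = 0.05)
  pos <- evac$lag_ms > 0
  expect_true(all(abs(evac$vac[pos]) < 3 * evac$se[pos]))
})

test_that("long unconfined uniform-model tracks recover alpha = 1 and the input D", {
  p <- physical_params()
  D <- stokes_einstein_diffusivity(p, 40 * water_viscosity(p$temperature_K))
  field <- build_viscosity_field(
    data.frame(length_nm = 1e6, width_nm = 1e6),
    model_config("uniform"), p)
  set.seed(77)
  ts <- make_ts(lapply(1:30, function(i)
    simulate_track(field, 3000, p, start = c(5e5, 5e5))),
    lengths_nm = 1e6, widths_nm = 1e6)
  fit <- bootstrap_fit_ci(ts, n_boot = 300, seed = 3)
  expect_true(fit$ci95["alpha_lo"] <= 1 && 1 <= fit$ci95["alpha_hi"])
  expect_true(fit$ci95["d_app_lo"] <= D && D <= fit$ci95["d_app_hi"])
})

test_that("bootstrap CIs are deterministic, degenerate for identical tracks, and cover the point estimate", {
  set.seed(31)
  m <- random_walk(40)
  ts_same <- make_ts(list(m, m, m))
  ci <- bootstrap_fit_ci(ts_same, n_boot = 100, seed = 2)
  expect_equal(unname(ci$ci95["alpha_lo"]), unname(ci$ci95["alpha_hi"]))
  expect_equal(unname(ci$ci95["d_app_lo"]), unname(ci$ci95["d_app_hi"]))
  ts <- make_ts(lapply(1:25, function(i) random_walk(40)))
  a <- bootstrap_fit_ci(ts, n_boot = 200, seed = 7)
  b <- bootstrap_fit_ci(ts, n_boot = 200, seed = 7)
  expect_identical(a$ci95, b$ci95)
  big <- bootstrap_fit_ci(ts, n_boot = 2000, seed = 1)
  expect_true(big$ci95["alpha_lo"] <= big$alpha &&
                big$alpha <= big$ci95["alpha_hi"])
  expect_true(big$ci95["d_app_lo"] <= big$d_app &&
                big$d_app <= big$ci95["d_app_hi"])
})
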