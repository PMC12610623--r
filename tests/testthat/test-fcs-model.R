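test_that("model amplitude and long-lag decay behave like 1/N and 0", {
  p <- fcs_params(n_molecules = 1, t_d1 = 1e-4, fraction_1 = 1)
  expect_equal(model_correlation(p, 0), 1)

  p2 <- fcs_params(n_molecules = 3, t_d1 = 1e-4, t_d2 = 1e-3,
                   fraction_1 = 0.4, triplet_amplitude = 0.2)
  far <- model_correlation(p2, 1e6 * p2$t_d2)
  expect_lt(far, 1e-3 / p2$n_molecules)
  # monotone decay toward the baseline on a lag grid
  g <- model_correlation(p2, log_lags(200))
  expect_true(all(diff(g) < 0))
})

test_that("model matches direct arithmetic evaluation of the formula", {
  # N=2, R=1, tD1=1e-4, omega=5, lag=1e-4: (1/2)*(1/2)*(1.04)^(-1/2)
  p <- fcs_params(n_molecules = 2, t_d1 = 1e-4, fraction_1 = 1,
                  aspect_ratio = 5)
  expect_equal(model_correlation(p, 1e-4), 0.25 / sqrt(1.04),
               tolerance = 1e-12)
  # vectorization preserves order
  lags <- c(1e-3, 1e-6, 1e-4)
  expect_equal(model_correlation(p, lags),
               vapply(lags, function(l) model_correlation(p, l), numeric(1)))
})

test_that("R = 1 collapses to the single-component model at all lags", {
  lags <- log_lags(100)
  p1 <- fcs_params(n_molecules = 4, t_d1 = 2e-4, t_d2 = 7e-3, fraction_1 = 1,
                   triplet_amplitude = 0.1)
  single <- (1 + lags / p1$t_d1)^-1 *
    (1 + lags / (p1$aspect_ratio^2 * p1$t_d1))^-0.5 *
    (1 + 0.1 * exp(-lags / p1$triplet_lifetime)) / 4
  expect_equal(model_correlation(p1, lags), single, tolerance = 1e-14)
})

test_that("parameter validation names the offending field", {
  expect_error(fcs_params(n_molecules = -1, t_d1 = 1e-4), "n_molecules")
  expect_error(fcs_params(1, t_d1 = 0), "t_d1")
  expect_error(fcs_params(1, 1e-4, fraction_1 = 1.2), "fraction_1")
  expect_error(fcs_params(1, 1e-4, aspect_ratio = 0.5), "aspect_ratio")
  p <- fcs_params(1, 1e-4)
  expect_error(model_correlation(p, c(1e-3, NaN)), "lag")
  expect_error(model_correlation(p, -1e-6), "lag")
})

test_that("beam waist calibration reproduces the reference-dye waists", {
  # Rhodamine 6G: D = 4.3e-10 m^2/s, tD = 525 us -> 0.95 um
  expect_equal(round(beam_waist_from_reference(4.3e-10, 525e-6) * 1e6, 2),
               0.95)
  # Cy5: D = 3.6e-10 m^2/s, tD = 271 us -> 0.62 um
  expect_equal(round(beam_waist_from_reference(3.6e-10, 271e-6) * 1e6, 2),
               0.62)
  expect_equal(beam_waist_from_reference(0.25, 1), 1)
  expect_error(beam_waist_from_reference(-1, 1), "reference_D")
})

test_that("diffusion_from_time inverts the calibration", {
  cal <- focal_volume_calibration(3.6e-10, 271e-6)
  # roundtrip identity on the reference point, to machine precision
  expect_equal(diffusion_from_time(271e-6, cal), 3.6e-10, tolerance = 1e-14)
  # D scales as 1/tD: 10x the reference time gives a tenth of D
  expect_equal(diffusion_from_time(2.71e-3, cal), 3.6e-11, tolerance = 1e-14)
  # waist 1 um, tD 0.25 s -> 1e-12 m^2/s
  cal2 <- focal_volume_calibration(1e-12, 0.25)
  expect_equal(cal2$beam_waist, 1e-6, tolerance = 1e-14)
  expect_equal(diffusion_from_time(0.25, cal2), 1e-12, tolerance = 1e-14)
  expect_error(diffusion_from_time(0, cal), "t_d")
})

test_that("Stokes-Einstein reproduces the printed hydrodynamic radii", {
  cond <- solvent_conditions() # 298.15 K, 0.89 cP
  expect_equal(signif(hydrodynamic_radius(0.207e-10, cond) * 1e9, 3), 11.9)
  expect_equal(signif(hydrodynamic_radius(0.111e-10, cond) * 1e9, 2), 22)
  # inverse proportionality: halving D doubles RH
  expect_equal(hydrodynamic_radius(0.5e-10, cond),
               2 * hydrodynamic_radius(1e-10, cond))
  # Stokes-Einstein product RH * D is constant at fixed conditions
  D <- c(1e-11, 3e-11, 2e-10)
  expect_equal(diff(range(hydrodynamic_radius(D, cond) * D)), 0,
               tolerance = 1e-30)
  expect_error(hydrodynamic_radius(-1e-10), "D")
})

test_that("focal volume is reported together with the aspect ratio used", {
  cal <- focal_volume_calibration(4.3e-10, 525e-6, aspect_ratio = 5)
  v <- focal_volume(cal)
  expect_equal(v$aspect_ratio, 5)
  expect_equal(v$volume_m3, pi^1.5 * cal$beam_waist^3 * 5, tolerance = 1e-14)
  expect_equal(focal_volume(cal, aspect_ratio = 10)$volume_um3,
               2 * v$volume_um3)
})
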