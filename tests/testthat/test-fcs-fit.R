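test_that("noiseless self-generated curves are recovered essentially exactly", {
  truth <- truth_params()
  fit <- fit_curve(noiseless_curve(), recovery_config())
  expect_true(fit$converged)
  expect_lt(fit$reduced_chi_square, 1e-8)
  for (nm in setdiff(fit$free, "baseline")) {
    expect_lt(abs(fit$params[[nm]] - truth[[nm]]) / abs(truth[[nm]]), 1e-4)
  }
  expect_lt(abs(fit$params$baseline), 1e-6)
})

test_that("free parameters are recovered within 10% at 0.5% noise", {
  truth <- truth_params()
  lags <- log_lags()
  g <- model_correlation(truth, lags)
  noise_sd <- 0.005 * g[1]
  rel_err <- sapply(1:20, function(seed) {
    set.seed(seed)
    curve <- correlation_curve(lags, g + rnorm(length(g), 0, noise_sd))
    fit <- fit_curve(curve, recovery_config(seed))
    vapply(setdiff(fit$free, "baseline"), function(nm) {
      abs(fit$params[[nm]] - truth[[nm]]) / abs(truth[[nm]])
    }, numeric(1))
  })
  expect_true(all(apply(rel_err, 1, median) < 0.10))
})

test_that("fit is invariant to rescaling lag units with rescaled times", {
  truth <- truth_params()
  lags <- log_lags()
  curve <- correlation_curve(lags, model_correlation(truth, lags))
  cfg_s <- fit_config(fixed = list(t_d1 = 5e-5, aspect_ratio = 5),
                      initial = list(triplet_lifetime = 5e-6))
  fit_s <- fit_curve(curve, cfg_s)
  # same curve expressed in milliseconds-as-seconds (lags / 1000), with the
  # fixed t_d1, time bounds and time initials scaled identically
  curve_ms <- correlation_curve(lags / 1000, curve$values)
  cfg_ms <- fit_config(
    fixed = list(t_d1 = 5e-5 / 1000, aspect_ratio = 5),
    initial = list(triplet_lifetime = 5e-6 / 1000),
    bounds = list(t_d2 = c(1e-12, 1e-2), triplet_lifetime = c(1e-12, 1e-3)))
  fit_ms <- fit_curve(curve_ms, cfg_ms)
  expect_equal(fit_ms$params$t_d2 * 1000, fit_s$params$t_d2,
               tolerance = 1e-6)
  expect_equal(fit_ms$params$n_molecules, fit_s$params$n_molecules,
               tolerance = 1e-6)
})

test_that("single-component data fit with two components degenerates sanely", {
  single <- fcs_params(n_molecules = 2, t_d1 = 2e-4, fraction_1 = 1)
  lags <- log_lags()
  curve <- correlation_curve(lags, model_correlation(single, lags))
  cfg <- fit_config(fixed = list(aspect_ratio = 5, triplet_amplitude = 0,
                                 triplet_lifetime = 5e-6, baseline = 0))
  fit <- fit_curve(curve, cfg)
  r <- fit$params$fraction_1
  degenerate <- r < 0.05 || r > 0.95 ||
    abs(fit$params$t_d1 - fit$params$t_d2) / fit$params$t_d2 < 0.05
  expect_true(degenerate)
  # no hand-tried lattice point beats the optimizer (coarse lattice,
  # deliberately not containing the generating parameters)
  grid <- expand.grid(n = c(1.5, 2.5, 4), td = c(1.2e-4, 3e-4, 6e-4),
                      r = c(0.25, 0.5, 0.75))
  grid_chisq <- apply(grid, 1, function(row) {
    p <- fcs_params(row["n"], row["td"], row["td"] * 2, row["r"],
                    aspect_ratio = 5)
    sum((curve$values - model_correlation(p, lags))^2) / (length(lags) - 4)
  })
  expect_lte(fit$reduced_chi_square, min(grid_chisq))
})

test_that("component relabeling keeps t_d1 <= t_d2", {
  truth <- truth_params()
  lags <- log_lags()
  curve <- correlation_curve(lags, model_correlation(truth, lags))
  # both diffusion times free, started with the labels swapped
  cfg <- fit_config(
    fixed = list(aspect_ratio = 5, triplet_amplitude = 0.15,
                 triplet_lifetime = 5e-6, baseline = 0),
    initial = list(t_d1 = 2e-3, t_d2 = 4e-5, fraction_1 = 0.7))
  fit <- fit_curve(curve, cfg)
  expect_lte(fit$params$t_d1, fit$params$t_d2)
})

test_that("degenerate inputs are rejected or flagged, not silently fit", {
  flat <- correlation_curve(c(1e-6, 1e-5, 1e-4), rep(0.5, 3))
  expect_error(fit_curve(flat), "constant")
  short <- correlation_curve(c(1e-6, 1e-5), c(1, 0.5))
  expect_error(fit_curve(short, recovery_config()), "fewer points")
})

test_that("diffusion times pool across repeats with honest standard errors", {
  res <- lapply(c(500e-6, 525e-6, 550e-6), stub_fit_result)
  pooled <- mean_diffusion_time(res, component = 2)
  expect_equal(pooled$mean, 525e-6)
  expect_equal(pooled$se, sd(c(500, 525, 550)) / sqrt(3) * 1e-6)
  expect_equal(round(pooled$se * 1e6, 1), 14.4)

  one <- mean_diffusion_time(res[1], component = 2)
  expect_equal(one$mean, 500e-6)
  expect_false(one$se_defined)
  expect_equal(one$se, 0)

  same <- mean_diffusion_time(rep(res[2], 3), component = 2)
  expect_equal(same$se, 0)

  unconv <- stub_fit_result(1e-3)
  unconv$converged <- FALSE
  expect_error(mean_diffusion_time(list(unconv)), "converged")
  expect_error(mean_diffusion_time(list()), "converged")
})

test_that("analyze_sample chains fit, calibration and Stokes-Einstein", {
  # synthetic curve whose slow component maps onto the printed D and RH:
  # with Wxy = 0.95 um, choose tD2 so that Wxy^2/(4 tD2) = 0.207e-10 m^2/s
  cal <- focal_volume_calibration(4.3e-10, 525e-6) # Wxy ~ 0.95 um
  td2 <- cal$beam_waist^2 / (4 * 0.207e-10)
  truth <- fcs_params(n_molecules = 3, t_d1 = 525e-6, t_d2 = td2,
                      fraction_1 = 0.25, aspect_ratio = 5)
  lags <- log_lags(80, 1e-6, 10)
  curve <- correlation_curve(lags, model_correlation(truth, lags))
  cfg <- fit_config(fixed = list(t_d1 = 525e-6, aspect_ratio = 5,
                                 triplet_amplitude = 0,
                                 triplet_lifetime = 5e-6))
  props <- analyze_sample(curve, cfg, cal, component = 2)
  expect_equal(signif(props$diffusion_coefficient * 1e10, 3), 0.207,
               tolerance = 1e-3)
  expect_equal(signif(props$hydrodynamic_radius * 1e9, 3), 11.9)

  # the Diversa LNP row: D = 0.111e-10 with the Cy5 calibration -> 22 nm
  cal5 <- focal_volume_calibration(3.6e-10, 271e-6) # Wxy ~ 0.62 um
  td2b <- cal5$beam_waist^2 / (4 * 0.111e-10)
  truth_b <- fcs_params(n_molecules = 3, t_d1 = 271e-6, t_d2 = td2b,
                        fraction_1 = 0.25, aspect_ratio = 5)
  curve_b <- correlation_curve(lags, model_correlation(truth_b, lags))
  cfg_b <- fit_config(fixed = list(t_d1 = 271e-6, aspect_ratio = 5,
                                   triplet_amplitude = 0,
                                   triplet_lifetime = 5e-6))
  props_b <- analyze_sample(curve_b, cfg_b, cal5, component = 2)
  expect_equal(signif(props_b$hydrodynamic_radius * 1e9, 2), 22)

  # calibration dye analyzed against its own calibration returns reference D
  dye <- fcs_params(n_molecules = 2, t_d1 = 1e-6, t_d2 = 271e-6,
                    fraction_1 = 0, aspect_ratio = 5)
  dye_curve <- correlation_curve(lags, model_correlation(dye, lags))
  props_dye <- analyze_sample(dye_curve, fit_config(), cal5, component = 2)
  expect_equal(props_dye$diffusion_coefficient, 3.6e-10, tolerance = 1e-4)
})
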