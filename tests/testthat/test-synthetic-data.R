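test_that("config validation catches unphysical simulation settings", {
  expect_error(fcs_sim_config(3.6e-10, 10, 1e4, 0.3e-6, time_step = 1e-3,
                              duration = 1),
               "time_step")
  expect_error(fcs_sim_config(3.6e-10, 10, 1e4, 0.3e-6,
                              box_half_widths = c(1e-6, 1e-6, 1e-6)),
               "box_half_widths")
  expect_error(fcs_sim_config(3.6e-10, 10.5, 1e4, 0.3e-6),
               "species_counts")
})

test_that("no emission yields an empty stream", {
  cfg <- fcs_sim_config(3.6e-10, 5, brightness = 0, beam_waist = 0.3e-6,
                        duration = 0.01, time_step = 2e-6,
                        background_rate = 0, seed = 1)
  expect_length(simulate_fcs_stream(cfg)$timestamps, 0)
})

test_that("an immobile particle at the focus emits at the Poisson rate", {
  B <- 1e4
  cfg <- fcs_sim_config(0, 1, B, 0.3e-6, duration = 10, time_step = 1e-4,
                        initial_positions = matrix(0, 1, 3), seed = 2)
  n <- length(simulate_fcs_stream(cfg)$timestamps)
  expect_lt(abs(n - B * 10), 4 * sqrt(B * 10))
})

test_that("same seed gives identical streams, different seed does not", {
  cfg <- fcs_sim_config(3.6e-10, 10, 1e5, 0.3e-6, duration = 0.02,
                        time_step = 2e-6, seed = 9)
  s1 <- simulate_fcs_stream(cfg)
  s2 <- simulate_fcs_stream(cfg)
  expect_identical(s1$timestamps, s2$timestamps)
  cfg$seed <- 10L
  expect_false(identical(simulate_fcs_stream(cfg)$timestamps, s1$timestamps))
})

test_that("mean count rate matches the Gaussian-profile expectation", {
  rates <- sapply(c(3, 4, 5), function(seed) {
    cfg <- fcs_sim_config(3.6e-10, 40, 2e5, 0.3e-6, duration = 0.3,
                          time_step = 2e-6, seed = seed)
    s <- simulate_fcs_stream(cfg)
    length(s$timestamps) / s$duration
  })
  cfg <- fcs_sim_config(3.6e-10, 40, 2e5, 0.3e-6, duration = 0.3,
                        time_step = 2e-6, seed = 3)
  expected <- fcs_sim_truth(cfg)$count_rate
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - expected), max(3 * se, 0.05 * expected))
})

test_that("triplet blinking reduces the emitted rate by the dark fraction", {
  B <- 2e4
  base <- fcs_sim_config(0, 1, B, 0.3e-6, duration = 5, time_step = 1e-5,
                         initial_positions = matrix(0, 1, 3), seed = 4)
  dark <- fcs_sim_config(0, 1, B, 0.3e-6, duration = 5, time_step = 1e-5,
                         initial_positions = matrix(0, 1, 3),
                         triplet = list(on_rate = 1e4, off_rate = 3e4),
                         seed = 4)
  n_base <- length(simulate_fcs_stream(base)$timestamps)
  n_dark <- length(simulate_fcs_stream(dark)$timestamps)
  # stationary bright fraction off/(on+off) = 0.75
  expect_equal(n_dark / n_base, 0.75, tolerance = 0.05)
})

test_that("simulated stream supports transit-time recovery end to end", {
  cfg <- fcs_sim_config(3.6e-10, 40, 2e5, 0.3e-6, aspect_ratio = 5,
                        duration = 1.5, time_step = 2e-6, seed = 7)
  truth <- fcs_sim_truth(cfg)
  res <- run_fcs_pipeline(cfg, seed = 7)
  expect_true(res$fit$converged)
  expect_lt(abs(res$fit$params$t_d2 - truth$t_d) / truth$t_d, 0.2)
})

test_that("noiseless stacks peak exactly at the prescribed slices", {
  cfg <- grid_stack_config(offsets = rep(17L, 12),
                           z1 = c(10L, rep(40L, 11)), noise_sd = 0)
  st <- simulate_two_channel_stack(cfg)
  rois <- grid_rois(cfg)
  expect_equal(as.integer(peak_slice(z_profile(st$ch1, rois[[1]]))), 10L)
  expect_equal(as.integer(peak_slice(z_profile(st$ch2, rois[[1]]))), 27L)
  rep17 <- axial_offsets(st$ch1, st$ch2, rois)
  expect_true(all(rep17$per_roi$delta_z == 17L))
  expect_equal(unname(rep17$summary[c("mean", "sd", "median")]), c(17, 0, 17))

  # identical peak slices in both channels: delta_z = 0 everywhere
  cfg0 <- grid_stack_config(offsets = rep(0L, 12), noise_sd = 0)
  st0 <- simulate_two_channel_stack(cfg0)
  rep0 <- axial_offsets(st0$ch1, st0$ch2, grid_rois(cfg0))
  expect_true(all(rep0$per_roi$delta_z == 0L))

  # same seed -> identical stacks
  st0b <- simulate_two_channel_stack(cfg0)
  expect_identical(st0, st0b)
})
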