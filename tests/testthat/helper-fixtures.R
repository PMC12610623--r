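# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures on disk.

# Two-component + triplet ground truth used across fitting tests.
truth_params <- function() {
  fcs_params(n_molecules = 5, t_d1 = 5e-5, t_d2 = 1e-3, fraction_1 = 0.3,
             aspect_ratio = 5, triplet_amplitude = 0.15,
             triplet_lifetime = 5e-6, baseline = 0)
}

log_lags <- function(n = 64, from = 1e-6, to = 1) {
  10^seq(log10(from), log10(to), length.out = n)
}

noiseless_curve <- function(params = truth_params(), lags = log_lags()) {
  correlation_curve(lags, model_correlation(params, lags))
}

# Fit config matching the free/fixed split of the recovery tests: t_d1 and
# the aspect ratio pinned, everything else free.
recovery_config <- function(seed = 1L) {
  fit_config(fixed = list(t_d1 = 5e-5, aspect_ratio = 5), seed = seed)
}

# Minimal converged fit result carrying a given slow diffusion time, for
# pooling tests that do not need a real optimization.
stub_fit_result <- function(t_d2, t_d1 = 1e-6) {
  structure(
    list(params = fcs_params(n_molecules = 1, t_d1 = t_d1, t_d2 = t_d2,
                             fraction_1 = 0),
         stderr = numeric(0), reduced_chi_square = 0, converged = TRUE,
         n_points = 0L, free = character(0)),
    class = "fit_result")
}

# Well-separated blob layout for the two-channel stack tests: a 4 x 3 grid
# in an 80 x 80 frame, 121 slices, with per-blob axial offsets supplied.
grid_stack_config <- function(offsets, z1 = NULL, noise_sd = 0, seed = 1L) {
  centers <- as.matrix(expand.grid(x = c(12, 30, 48, 66), y = c(14, 36, 58)))
  n <- nrow(centers)
  stopifnot(length(offsets) == n)
  if (is.null(z1)) z1 <- rep(40L, n)
  stack_sim_config(shape = c(121, 80, 80), blob_centers = centers,
                   z_peak_channel1 = z1,
                   z_peak_channel2 = pmin(z1 + offsets, 120),
                   axial_sigma = 2, lateral_sigma = 3, amplitude = 2000,
                   noise_sd = noise_sd, seed = seed)
}

grid_rois <- function(config) {
  centers <- config$blob_centers
  lapply(seq_len(nrow(centers)), function(i) {
    roi(centers[i, 1] - 5, centers[i, 2] - 5, 11, 11, paste0("roi", i))
  })
}
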