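# Synthetic-data generators with known ground truth: Brownian-dynamics
# photon streams from a 3D Gaussian detection volume, and two-channel
# Gaussian-blob z-stacks with prescribed axial offsets.

#' Configuration for the Brownian-dynamics FCS simulator
#'
#' Particles of one or more species diffuse in a periodic box through a 3D
#' Gaussian detection profile
#' `W(x,y,z) = exp(-2 (x^2+y^2) / Wxy^2 - 2 z^2 / (omega * Wxy)^2)`.
#' Per time step each particle contributes an expected photon count
#' `brightness * W(position) * dt` (zero while in the triplet dark state);
#' photon counts are Poisson draws and are spread uniformly inside the step.
#'
#' @param diffusion_coefficients Per-species D, m^2/s (>= 0; 0 pins a
#'   particle in place, useful for brightness checks).
#' @param species_counts Per-species particle numbers in the box (integers).
#' @param brightness Per-species peak photon rate at the focus center,
#'   counts/s. Recycled across species.
#' @param beam_waist Radial 1/e^2 radius Wxy, meters.
#' @param aspect_ratio Axial/radial aspect ratio omega (>= 1).
#' @param box_half_widths Half-extent of the periodic box in x, y, z,
#'   meters. Default `5 * c(Wxy, Wxy, omega*Wxy)` — five focal radii per
#'   axis, the smallest box at which boundary wrap-around is negligible.
#' @param time_step Simulation step, seconds; must resolve the focal transit
#'   (`time_step < Wxy^2 / (40 * max D)` is enforced).
#' @param duration Total simulated time, seconds.
#' @param background_rate Uncorrelated background counts/s (>= 0).
#' @param initial_positions Optional `sum(species_counts)` x 3 matrix of
#'   starting coordinates (meters, box-centered); defaults to uniform in the
#'   box. Mainly for deterministic checks, e.g. pinning an immobile particle
#'   at the focus.
#' @param triplet Optional `list(on_rate=, off_rate=)`, both in 1/s: a
#'   two-state telegraph process per particle. `on_rate` is the rate of
#'   entering the dark (triplet) state, `off_rate` the rate of returning.
#'   The stationary dark fraction is `F = on/(on+off)` and the blinking
#'   relaxes with correlation time `1/(on+off)`, producing the
#'   `(1 + A_T exp(-t/t_T))` signature with `A_T = F/(1-F)`.
#' @param seed Integer seed; identical configs give identical streams.
#' @return An object of class `fcs_sim_config`.
#' @export
fcs_sim_config <- function(diffusion_coefficients, species_counts,
                           brightness, beam_waist, aspect_ratio = 5,
                           box_half_widths = NULL, time_step = 1e-6,
                           duration = 1, background_rate = 0,
                           initial_positions = NULL, triplet = NULL,
                           seed = 1L) {
  .check_number(diffusion_coefficients, "diffusion_coefficients",
                nonnegative = TRUE, len = NULL)
  ns <- length(diffusion_coefficients)
  .check_number(species_counts, "species_counts", positive = TRUE, len = ns)
  if (any(species_counts != round(species_counts))) {
    stop("'species_counts' must be whole numbers", call. = FALSE)
  }
  .check_number(brightness, "brightness", nonnegative = TRUE, len = NULL)
  brightness <- rep_len(brightness, ns)
  .check_number(beam_waist, "beam_waist", positive = TRUE)
  .check_number(aspect_ratio, "aspect_ratio", positive = TRUE)
  if (aspect_ratio < 1) stop("'aspect_ratio' must be >= 1", call. = FALSE)
  wz <- aspect_ratio * beam_waist
  if (is.null(box_half_widths)) {
    box_half_widths <- 5 * c(beam_waist, beam_waist, wz)
  }
  .check_number(box_half_widths, "box_half_widths", positive = TRUE, len = 3)
  if (box_half_widths[1] < 5 * beam_waist ||
      box_half_widths[2] < 5 * beam_waist ||
      box_half_widths[3] < 5 * wz) {
    stop("'box_half_widths' must be at least 5 focal radii per axis",
         call. = FALSE)
  }
  .check_number(time_step, "time_step", positive = TRUE)
  .check_number(duration, "duration", positive = TRUE)
  if (time_step >= duration) {
    stop("'time_step' must be smaller than 'duration'", call. = FALSE)
  }
  max_d <- max(diffusion_coefficients)
  if (max_d > 0 && time_step >= beam_waist^2 / (40 * max_d)) {
    stop("'time_step' too coarse: must be well below the focal transit time ",
         "beam_waist^2/(4 D)", call. = FALSE)
  }
  .check_number(background_rate, "background_rate", nonnegative = TRUE)
  if (!is.null(initial_positions)) {
    initial_positions <- as.matrix(initial_positions)
    if (nrow(initial_positions) != sum(species_counts) ||
        ncol(initial_positions) != 3) {
      stop("'initial_positions' must be a sum(species_counts) x 3 matrix",
           call. = FALSE)
    }
  }
  if (!is.null(triplet)) {
    .check_number(triplet$on_rate, "triplet$on_rate", positive = TRUE)
    .check_number(triplet$off_rate, "triplet$off_rate", positive = TRUE)
  }
  structure(
    list(diffusion_coefficients = diffusion_coefficients,
         species_counts = as.integer(species_counts),
         brightness = brightness, beam_waist = beam_waist,
         aspect_ratio = aspect_ratio, box_half_widths = box_half_widths,
         time_step = time_step, duration = duration,
         background_rate = background_rate,
         initial_positions = initial_positions, triplet = triplet,
         seed = as.integer(seed)),
    class = "fcs_sim_config"
  )
}

#' Ground truth implied by an FCS simulation config
#'
#' Analytic expectations used to validate the pipeline against the
#' generator: per-species diffusion correlation time `t_D = Wxy^2/(4 D)`,
#' effective focal-volume occupancy
#' `N_eff = count * V_eff / V_box` with `V_eff = pi^(3/2) Wxy^2 (omega Wxy)`,
#' the zero-lag amplitude `1/sum(N_eff)` (single species), and the expected
#' mean count rate (Gaussian-profile integral over the box, ignoring the
#' negligible truncation beyond five focal radii).
#'
#' @param config An [fcs_sim_config()].
#' @return List with `t_d`, `n_eff`, `amplitude`, `count_rate`.
#' @export
fcs_sim_truth <- function(config) {
  stopifnot(inherits(config, "fcs_sim_config"))
  w <- config$beam_waist
  wz <- config$aspect_ratio * w
  v_box <- prod(2 * config$box_half_widths)
  v_eff <- pi^1.5 * w^2 * wz
  n_eff <- config$species_counts * v_eff / v_box
  t_d <- ifelse(config$diffusion_coefficients > 0,
                w^2 / (4 * config$diffusion_coefficients), Inf)
  emit_frac <- 1
  if (!is.null(config$triplet)) {
    tr <- config$triplet
    emit_frac <- tr$off_rate / (tr$on_rate + tr$off_rate)
  }
  mean_w <- (pi / 2)^1.5 * w^2 * wz / v_box # box-average of the profile
  rate <- config$background_rate +
    sum(config$species_counts * config$brightness) * mean_w * emit_frac
  list(t_d = t_d, n_eff = n_eff, amplitude = 1 / sum(n_eff),
       count_rate = rate)
}

# Alternating bright/dark dwell times for one particle; returns the
# emitting indicator evaluated at the supplied times.
.telegraph_indicator <- function(times, duration, on_rate, off_rate) {
  p_bright <- off_rate / (on_rate + off_rate)
  state <- stats::runif(1) < p_bright
  switches <- numeric(0)
  t <- 0
  s <- state
  while (t < duration) {
    dwell <- stats::rexp(1, rate = if (s) on_rate else off_rate)
    t <- t + dwell
    switches <- c(switches, t)
    s <- !s
  }
  # state at time x: initial state flipped once per switch before x
  n_flips <- findInterval(times, switches)
  as.numeric(ifelse(n_flips %% 2 == 0, state, !state))
}

#' Simulate an FCS photon stream by Brownian dynamics
#'
#' Each particle performs independent Gaussian steps
#' (`sd = sqrt(2 D dt)` per coordinate) with periodic wrapping in the box;
#' per step the detected rate is the sum of per-particle Gaussian-profile
#' brightnesses plus background, photon counts are drawn Poisson, and
#' timestamps are placed uniformly inside the step. Deterministic given the
#' config seed; the caller's RNG state is untouched.
#'
#' @param config An [fcs_sim_config()].
#' @return A [photon_stream()] with the config attached as attribute
#'   `"config"`.
#' @export
#' @examples
#' cfg <- fcs_sim_config(3.6e-10, 10, 5e4, 0.3e-6, duration = 0.05,
#'                       time_step = 2e-6, seed = 7)
#' s <- simulate_fcs_stream(cfg)
simulate_fcs_stream <- function(config) {
  stopifnot(inherits(config, "fcs_sim_config"))
  .with_seed(config$seed, {
    dt <- config$time_step
    n_steps <- floor(config$duration / dt)
    hw <- config$box_half_widths
    w2 <- config$beam_waist^2
    wz2 <- (config$aspect_ratio * config$beam_waist)^2
    m_total <- sum(config$species_counts)
    species <- rep(seq_along(config$species_counts), config$species_counts)
    bright <- config$brightness[species]
    step_sd <- sqrt(2 * config$diffusion_coefficients[species] * dt)

    # initial positions: uniform in the box (m_total x 3) unless supplied
    pos <- if (!is.null(config$initial_positions)) {
      config$initial_positions
    } else {
      cbind(stats::runif(m_total, -hw[1], hw[1]),
            stats::runif(m_total, -hw[2], hw[2]),
            stats::runif(m_total, -hw[3], hw[3]))
    }

    # triplet emitting indicators, precomputed per particle at step times
    emit <- NULL
    if (!is.null(config$triplet)) {
      step_times <- (seq_len(n_steps) - 1) * dt
      emit <- vapply(seq_len(m_total), function(i) {
        .telegraph_indicator(step_times, config$duration,
                             config$triplet$on_rate,
                             config$triplet$off_rate)
      }, numeric(n_steps))
    }

    chunk <- max(1000L, min(n_steps, floor(6e6 / max(1, 3 * m_total))))
    ts_parts <- vector("list", ceiling(n_steps / chunk))
    part <- 0L
    done <- 0L
    while (done < n_steps) {
      L <- min(chunk, n_steps - done)
      if (any(step_sd > 0)) {
        # columns ordered [x_1..x_M, y_1..y_M, z_1..z_M]
        incr <- matrix(stats::rnorm(L * 3 * m_total), nrow = L)
        incr <- sweep(incr, 2, rep(step_sd, times = 3), `*`)
        walk <- apply(incr, 2, cumsum)
        if (L == 1) walk <- matrix(walk, nrow = 1)
      } else {
        walk <- matrix(0, nrow = L, ncol = 3 * m_total)
      }
      base <- c(pos[, 1], pos[, 2], pos[, 3])
      traj <- sweep(walk, 2, base, `+`)
      hw_rep <- rep(hw, each = m_total)
      traj <- sweep(traj, 2, hw_rep, `+`)
      traj <- sweep(traj, 2, 2 * hw_rep, `%%`)
      traj <- sweep(traj, 2, hw_rep, `-`)

      xi <- traj[, seq_len(m_total), drop = FALSE]
      yi <- traj[, m_total + seq_len(m_total), drop = FALSE]
      zi <- traj[, 2 * m_total + seq_len(m_total), drop = FALSE]
      profile <- exp(-2 * (xi^2 + yi^2) / w2 - 2 * zi^2 / wz2)
      if (!is.null(emit)) {
        profile <- profile * emit[done + seq_len(L), , drop = FALSE]
      }
      rate <- as.numeric(profile %*% bright) + config$background_rate
      k <- stats::rpois(L, rate * dt)
      tot <- sum(k)
      if (tot > 0) {
        starts <- (done + which(k > 0) - 1) * dt
        reps <- k[k > 0]
        part <- part + 1L
        ts_parts[[part]] <- rep(starts, reps) + stats::runif(tot, 0, dt)
      }
      pos <- cbind(traj[L, seq_len(m_total)],
                   traj[L, m_total + seq_len(m_total)],
                   traj[L, 2 * m_total + seq_len(m_total)])
      done <- done + L
    }
    ts <- sort(unlist(ts_parts[seq_len(part)]))
    out <- photon_stream(ts, duration = n_steps * dt, channel_id = "sim")
    attr(out, "config") <- config
    out
  })
}

#' Configuration for the two-channel z-stack simulator
#'
#' Each channel is a sum of 3D Gaussian blobs sharing lateral centers but
#' with channel-specific axial peak slices, plus Gaussian read noise, clipped
#' at zero and quantized to integer counts (16-bit range). Slice indices are
#' 0-based.
#'
#' @param shape `c(n_slices, height, width)` in voxels.
#' @param blob_centers n x 2 matrix of lateral centers `(x, y)` in pixels
#'   (0-based).
#' @param z_peak_channel1,z_peak_channel2 Per-blob peak slice indices,
#'   0-based, within `[0, n_slices)`.
#' @param axial_sigma Axial Gaussian width, slices (> 0).
#' @param lateral_sigma Lateral Gaussian width, pixels (> 0).
#' @param amplitude Peak blob intensity, counts.
#' @param noise_sd Gaussian noise standard deviation, counts (>= 0).
#' @param seed Integer seed.
#' @return An object of class `stack_sim_config`.
#' @export
stack_sim_config <- function(shape, blob_centers, z_peak_channel1,
                             z_peak_channel2, axial_sigma = 3,
                             lateral_sigma = 2, amplitude = 1000,
                             noise_sd = 0, seed = 1L) {
  .check_number(shape, "shape", positive = TRUE, len = 3)
  blob_centers <- as.matrix(blob_centers)
  if (ncol(blob_centers) != 2) {
    stop("'blob_centers' must have two columns (x, y)", call. = FALSE)
  }
  nb <- nrow(blob_centers)
  .check_number(z_peak_channel1, "z_peak_channel1", nonnegative = TRUE,
                len = nb)
  .check_number(z_peak_channel2, "z_peak_channel2", nonnegative = TRUE,
                len = nb)
  if (any(z_peak_channel1 >= shape[1]) || any(z_peak_channel2 >= shape[1])) {
    stop("peak slice indices must lie within [0, n_slices)", call. = FALSE)
  }
  .check_number(axial_sigma, "axial_sigma", positive = TRUE)
  .check_number(lateral_sigma, "lateral_sigma", positive = TRUE)
  .check_number(amplitude, "amplitude", positive = TRUE)
  .check_number(noise_sd, "noise_sd", nonnegative = TRUE)
  structure(
    list(shape = as.integer(shape), blob_centers = blob_centers,
         z_peak_channel1 = z_peak_channel1,
         z_peak_channel2 = z_peak_channel2, axial_sigma = axial_sigma,
         lateral_sigma = lateral_sigma, amplitude = amplitude,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "stack_sim_config"
  )
}

.render_channel <- function(config, z_peaks) {
  ns <- config$shape[1]; h <- config$shape[2]; w <- config$shape[3]
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h) # pixel x per column
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h) # pixel y per row
  lateral <- lapply(seq_len(nrow(config$blob_centers)), function(b) {
    cx <- config$blob_centers[b, 1]; cy <- config$blob_centers[b, 2]
    exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * config$lateral_sigma^2))
  })
  stack <- array(0, dim = c(ns, h, w))
  for (k in 0:(ns - 1)) {
    slice <- matrix(0, h, w)
    for (b in seq_along(lateral)) {
      ax <- exp(-(k - z_peaks[b])^2 / (2 * config$axial_sigma^2))
      slice <- slice + config$amplitude * ax * lateral[[b]]
    }
    stack[k + 1, , ] <- slice
  }
  stack
}

#' Simulate a two-channel confocal z-stack
#'
#' @param config A [stack_sim_config()].
#' @return List with integer-valued arrays `ch1` and `ch2`, each of dim
#'   `c(n_slices, height, width)`, and the `config`.
#' @export
simulate_two_channel_stack <- function(config) {
  stopifnot(inherits(config, "stack_sim_config"))
  .with_seed(config$seed, {
    ch1 <- .render_channel(config, config$z_peak_channel1)
    ch2 <- .render_channel(config, config$z_peak_channel2)
    if (config$noise_sd > 0) {
      ch1 <- ch1 + stats::rnorm(length(ch1), 0, config$noise_sd)
      ch2 <- ch2 + stats::rnorm(length(ch2), 0, config$noise_sd)
    }
    clipq <- function(a) {
      a <- round(pmax(a, 0))
      array(pmin(a, 65535), dim = dim(a))
    }
    list(ch1 = clipq(ch1), ch2 = clipq(ch2), config = config)
  })
}
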