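#' Parameter set for the two-component + triplet FCS model
#'
#' Bundles the parameters of the fluctuation autocorrelation model used
#' throughout the package:
#' \deqn{G(t) = \frac{1}{N}\left[R\left(1+\frac{t}{t_{D,1}}\right)^{-1}
#'   \left(1+\frac{t}{\omega^2 t_{D,1}}\right)^{-1/2} +
#'   (1-R)\left(1+\frac{t}{t_{D,2}}\right)^{-1}
#'   \left(1+\frac{t}{\omega^2 t_{D,2}}\right)^{-1/2}\right]
#'   \left(1 + A_T e^{-t/t_T}\right) + b_0}
#' where \eqn{N} is the mean number of molecules in the focal volume,
#' \eqn{t_{D,1}} and \eqn{t_{D,2}} the diffusion correlation times of the two
#' species weighted by \eqn{R}, \eqn{\omega} the axial/radial aspect ratio of
#' the focal volume, \eqn{A_T} and \eqn{t_T} the triplet amplitude and
#' lifetime, and \eqn{b_0} the baseline. The triplet factor multiplies the
#' whole two-component sum (no \eqn{1-A_T} renormalization). All times are in
#' seconds.
#'
#' @param n_molecules Mean focal-volume occupancy N (> 0).
#' @param t_d1,t_d2 Diffusion correlation times of components 1 and 2,
#'   seconds (> 0).
#' @param fraction_1 Weight R of component 1 in `[0, 1]`.
#' @param aspect_ratio Axial/radial extent omega of the focal volume (>= 1).
#' @param triplet_amplitude Triplet amplitude A_T (>= 0).
#' @param triplet_lifetime Triplet correlation time t_T, seconds (> 0).
#' @param baseline Asymptotic curve value b_0.
#' @return An object of class `fcs_params` (a validated named list).
#' @seealso [model_correlation()], [fit_curve()]
#' @export
#' @examples
#' p <- fcs_params(n_molecules = 2, t_d1 = 1e-4, fraction_1 = 1, aspect_ratio = 5)
#' model_correlation(p, 1e-4)
fcs_params <- function(n_molecules, t_d1, t_d2 = t_d1, fraction_1 = 1,
                       aspect_ratio = 5, triplet_amplitude = 0,
                       triplet_lifetime = 5e-6, baseline = 0) {
  .check_number(n_molecules, "n_molecules", positive = TRUE)
  .check_number(t_d1, "t_d1", positive = TRUE)
  .check_number(t_d2, "t_d2", positive = TRUE)
  .check_fraction(fraction_1, "fraction_1")
  .check_number(aspect_ratio, "aspect_ratio", positive = TRUE)
  if (aspect_ratio < 1) {
    stop("'aspect_ratio' must be >= 1", call. = FALSE)
  }
  .check_number(triplet_amplitude, "triplet_amplitude", nonnegative = TRUE)
  .check_number(triplet_lifetime, "triplet_lifetime", positive = TRUE)
  .check_number(baseline, "baseline")
  structure(
    list(
      n_molecules = n_molecules, t_d1 = t_d1, t_d2 = t_d2,
      fraction_1 = fraction_1, aspect_ratio = aspect_ratio,
      triplet_amplitude = triplet_amplitude,
      triplet_lifetime = triplet_lifetime, baseline = baseline
    ),
    class = "fcs_params"
  )
}

#' @export
print.fcs_params <- function(x, ...) {
  cat("FCS model parameters (two-component + triplet)\n")
  cat(sprintf("  N = %.4g, R = %.3f\n", x$n_molecules, x$fraction_1))
  cat(sprintf("  t_d1 = %.4g s, t_d2 = %.4g s, omega = %.3g\n",
              x$t_d1, x$t_d2, x$aspect_ratio))
  cat(sprintf("  triplet: A_T = %.4g, t_T = %.4g s; baseline b0 = %.4g\n",
              x$triplet_amplitude, x$triplet_lifetime, x$baseline))
  invisible(x)
}

.diffusion_term <- function(lag, t_d, omega) {
  (1 + lag / t_d)^-1 * (1 + lag / (omega^2 * t_d))^-0.5
}

#' Evaluate the FCS correlation model
#'
#' Closed-form evaluation of the two-component diffusion model with a triplet
#' term (see [fcs_params()]) at one or more lag times. Vectorizes over `lag`,
#' preserving order.
#'
#' @param params An [fcs_params()] object.
#' @param lag Lag time(s) in seconds, each >= 0.
#' @return Numeric vector of correlation values, one per lag.
#' @export
#' @examples
#' p <- fcs_params(n_molecules = 1, t_d1 = 1e-4)
#' model_correlation(p, 0) # 1/N = 1
model_correlation <- function(params, lag) {
  stopifnot(inherits(params, "fcs_params"))
  .check_number(lag, "lag", nonnegative = TRUE, len = NULL)
  R <- params$fraction_1
  w <- params$aspect_ratio
  diff_part <- R * .diffusion_term(lag, params$t_d1, w) +
    (1 - R) * .diffusion_term(lag, params$t_d2, w)
  triplet <- 1 + params$triplet_amplitude * exp(-lag / params$triplet_lifetime)
  diff_part * triplet / params$n_molecules + params$baseline
}

#' Beam waist from a reference dye
#'
#' Calibrates the radial 1/e^2 radius of the confocal focal volume from a
#' reference dye of known (literature) diffusion coefficient whose diffusion
#' correlation time was fitted on the same instrument: since
#' D = Wxy^2 / (4 t_D), the waist is Wxy = sqrt(4 D t_D).
#'
#' @param reference_D Literature diffusion coefficient of the calibration
#'   dye, m^2/s (> 0).
#' @param reference_t_d Fitted mean diffusion correlation time of the dye,
#'   seconds (> 0).
#' @return Beam waist Wxy in meters.
#' @export
#' @examples
#' beam_waist_from_reference(3.6e-10, 271e-6) * 1e6 # ~0.62 um (Cy5)
beam_waist_from_reference <- function(reference_D, reference_t_d) {
  .check_number(reference_D, "reference_D", positive = TRUE)
  .check_number(reference_t_d, "reference_t_d", positive = TRUE)
  sqrt(4 * reference_D * reference_t_d)
}

#' Focal-volume calibration object
#'
#' Stores a reference-dye calibration: the dye's literature diffusion
#' coefficient and fitted diffusion time, the derived beam waist
#' (`Wxy = sqrt(4 D t_D)`, exact by construction) and the aspect ratio used
#' when a focal volume is reported.
#'
#' @param reference_diffusion_coefficient m^2/s (> 0).
#' @param reference_diffusion_time seconds (> 0).
#' @param aspect_ratio Dimensionless omega (>= 1) carried along for
#'   focal-volume reporting.
#' @return An object of class `focal_volume_calibration`.
#' @seealso [diffusion_from_time()], [focal_volume()]
#' @export
#' @examples
#' cal <- focal_volume_calibration(4.3e-10, 525e-6)
#' cal$beam_waist * 1e6 # ~0.95 um (Rhodamine 6G)
focal_volume_calibration <- function(reference_diffusion_coefficient,
                                     reference_diffusion_time,
                                     aspect_ratio = 5) {
  .check_number(reference_diffusion_coefficient,
                "reference_diffusion_coefficient", positive = TRUE)
  .check_number(reference_diffusion_time, "reference_diffusion_time",
                positive = TRUE)
  .check_number(aspect_ratio, "aspect_ratio", positive = TRUE)
  structure(
    list(
      reference_diffusion_coefficient = reference_diffusion_coefficient,
      reference_diffusion_time = reference_diffusion_time,
      beam_waist = beam_waist_from_reference(reference_diffusion_coefficient,
                                             reference_diffusion_time),
      aspect_ratio = aspect_ratio
    ),
    class = "focal_volume_calibration"
  )
}

#' @export
print.focal_volume_calibration <- function(x, ...) {
  cat("Focal-volume calibration\n")
  cat(sprintf("  reference D  = %.3g m^2/s, t_D = %.4g s\n",
              x$reference_diffusion_coefficient, x$reference_diffusion_time))
  cat(sprintf("  beam waist   = %.3g m (%.2f um), omega = %.3g\n",
              x$beam_waist, x$beam_waist * 1e6, x$aspect_ratio))
  invisible(x)
}

#' Diffusion coefficient from a diffusion correlation time
#'
#' Converts a fitted diffusion correlation time to a diffusion coefficient
#' through the calibrated beam waist: D = Wxy^2 / (4 t_D).
#'
#' @param t_d Diffusion correlation time, seconds (> 0).
#' @param calibration A [focal_volume_calibration()].
#' @return Diffusion coefficient in m^2/s.
#' @export
diffusion_from_time <- function(t_d, calibration) {
  stopifnot(inherits(calibration, "focal_volume_calibration"))
  .check_number(t_d, "t_d", positive = TRUE, len = NULL)
  calibration$beam_waist^2 / (4 * t_d)
}

#' Solvent conditions for Stokes-Einstein conversion
#'
#' @param temperature Absolute temperature, kelvin (> 0). Default 298.15 K.
#' @param viscosity Dynamic viscosity, Pa s (> 0). Default 0.89 cP, water at
#'   25 degrees C.
#' @return An object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(temperature = DEFAULT_TEMPERATURE,
                               viscosity = DEFAULT_VISCOSITY) {
  .check_number(temperature, "temperature", positive = TRUE)
  .check_number(viscosity, "viscosity", positive = TRUE)
  structure(list(temperature = temperature, viscosity = viscosity),
            class = "solvent_conditions")
}

#' Stokes-Einstein hydrodynamic radius
#'
#' R_H = kB T / (6 pi eta D), with kB the CODATA Boltzmann constant. The
#' hydrodynamic radius is the radius of the sphere that would diffuse with
#' coefficient D in the given solvent; aggregation of labeled protein shows
#' up as an increased R_H.
#'
#' @param D Diffusion coefficient, m^2/s (> 0). Vectorized.
#' @param conditions A [solvent_conditions()] object.
#' @return Hydrodynamic radius in meters.
#' @export
#' @examples
#' hydrodynamic_radius(0.207e-10) * 1e9 # ~11.9 nm
hydrodynamic_radius <- function(D, conditions = solvent_conditions()) {
  stopifnot(inherits(conditions, "solvent_conditions"))
  .check_number(D, "D", positive = TRUE, len = NULL)
  kB * conditions$temperature / (6 * pi * conditions$viscosity * D)
}

#' Effective confocal focal volume
#'
#' V = pi^(3/2) * Wxy^2 * (omega * Wxy), the standard 3D-Gaussian effective
#' volume. The value is meaningful only together with the aspect ratio used,
#' which is therefore reported alongside.
#'
#' @param calibration A [focal_volume_calibration()].
#' @param aspect_ratio Optional omega override; defaults to the
#'   calibration's.
#' @return A list with `volume_m3`, `volume_um3` and `aspect_ratio`.
#' @export
focal_volume <- function(calibration, aspect_ratio = NULL) {
  stopifnot(inherits(calibration, "focal_volume_calibration"))
  w <- if (is.null(aspect_ratio)) calibration$aspect_ratio else aspect_ratio
  .check_number(w, "aspect_ratio", positive = TRUE)
  v <- pi^1.5 * calibration$beam_waist^2 * (w * calibration$beam_waist)
  list(volume_m3 = v, volume_um3 = v * 1e18, aspect_ratio = w)
}
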