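# Reagent dosimetry: per-cell dose arithmetic, molar-to-mass conversion,
# BCA linear calibration, and bioconjugation mass balance.

#' Per-cell reagent dose
#'
#' Dose per cell = applied volume x mass concentration / cell count. All
#' arithmetic is full precision; round with [format_dose()] (2 significant
#' figures) only for presentation.
#'
#' @param volume Applied reagent volume, microliters (> 0). Vectorized.
#' @param concentration Mass concentration, ng/uL (> 0).
#' @param cells Cell count per well (> 0).
#' @return Dose in ng per cell.
#' @export
#' @examples
#' dose_per_cell(75, 25, 20000) # 0.09375 ng sgRNA per cell
dose_per_cell <- function(volume, concentration, cells) {
  .check_number(volume, "volume", positive = TRUE, len = NULL)
  .check_number(concentration, "concentration", positive = TRUE, len = NULL)
  .check_number(cells, "cells", positive = TRUE, len = NULL)
  volume * concentration / cells
}

#' Reagent mass from a molar specification
#'
#' Converts concentration (uM) x volume (uL) x molecular weight (g/mol) to
#' nanograms: `conc * 1e-6 mol/L * vol * 1e-6 L * MW g/mol * 1e9 ng/g`.
#'
#' @param concentration Molar concentration, micromolar (> 0). Vectorized.
#' @param volume Volume, microliters (> 0).
#' @param molecular_weight g/mol (> 0); see [MW_CAS9], [MW_SGRNA_100NT],
#'   [MW_RNP] for defaults used with Cas9 reagents.
#' @return Mass in ng.
#' @export
#' @examples
#' mass_from_molar(3, 10, 160000) # 4800 ng
mass_from_molar <- function(concentration, volume, molecular_weight) {
  .check_number(concentration, "concentration", positive = TRUE, len = NULL)
  .check_number(volume, "volume", positive = TRUE, len = NULL)
  .check_number(molecular_weight, "molecular_weight", positive = TRUE,
                len = NULL)
  concentration * 1e-6 * volume * 1e-6 * molecular_weight * 1e9
}

#' Round a dose to printed precision
#'
#' Rounds to significant figures with halves away from zero (so 0.0125
#' prints as 0.013), the convention used for reported per-cell doses;
#' `signif()` rounds halves to even.
#'
#' @param dose Numeric dose(s).
#' @param digits Significant figures (default 2, the convention for per-cell
#'   doses).
#' @return Rounded numeric.
#' @export
format_dose <- function(dose, digits = 2) {
  .check_number(dose, "dose", len = NULL)
  out <- dose
  nz <- dose != 0
  mag <- floor(log10(abs(dose[nz])))
  unit <- 10^(mag - digits + 1)
  out[nz] <- sign(dose[nz]) *
    floor(abs(dose[nz]) / unit + 0.5 + 1e-9) * unit
  out
}

#' Fit a linear protein-assay calibration
#'
#' Ordinary least squares of absorbance (562 nm) on standard concentration,
#' as used for BCA quantification against BSA standards.
#'
#' @param concentration Standard concentrations, ug/mL (at least two
#'   distinct values).
#' @param absorbance Measured absorbances, same length.
#' @return An object of class `linear_calibration`: `slope` (absorbance per
#'   ug/mL), `intercept` (absorbance), `r_squared`.
#' @export
#' @examples
#' cal <- fit_linear_calibration(c(0, 50, 100), 0.0092 * c(0, 50, 100))
#' cal$slope
fit_linear_calibration <- function(concentration, absorbance) {
  .check_number(concentration, "concentration", nonnegative = TRUE,
                len = NULL)
  .check_number(absorbance, "absorbance", len = NULL)
  if (length(concentration) != length(absorbance)) {
    stop("'concentration' and 'absorbance' must have equal length",
         call. = FALSE)
  }
  if (length(unique(concentration)) < 2) {
    stop("at least two distinct 'concentration' values are required",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2),
    class = "linear_calibration"
  )
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("Linear calibration: A = %.4g x conc + %.4g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a linear calibration
#'
#' @param absorbance Measured absorbance(s).
#' @param cal A [fit_linear_calibration()] result (or any list with `slope`
#'   and `intercept`).
#' @return Concentration in ug/mL. Values below the blank (negative results)
#'   are returned as-is with a warning.
#' @export
concentration_from_absorbance <- function(absorbance, cal) {
  .check_number(absorbance, "absorbance", len = NULL)
  if (cal$slope == 0) stop("'slope' must be nonzero", call. = FALSE)
  conc <- (absorbance - cal$intercept) / cal$slope
  if (any(conc < 0)) {
    warning("absorbance below the calibration blank: negative concentration",
            call. = FALSE)
  }
  conc
}

#' Immobilization mass balance
#'
#' Accounting for a bioconjugation step: of `loaded` micrograms of complex,
#' `bound` remain on the particle surface; efficiency is the bound
#' percentage and the unbound remainder closes the balance exactly.
#'
#' @param loaded Loaded mass, ug (> 0).
#' @param bound Bound (immobilized) mass, ug, in `[0, loaded]`.
#' @return An object of class `mass_balance`: `loaded`, `bound`, `unbound`
#'   (ug) and `efficiency` (percent).
#' @export
#' @examples
#' immobilization_balance(100, 42.90) # 42.90% efficiency, 57.10 ug unbound
immobilization_balance <- function(loaded, bound) {
  .check_number(loaded, "loaded", positive = TRUE)
  .check_number(bound, "bound", nonnegative = TRUE)
  if (bound > loaded) {
    stop("'bound' cannot exceed 'loaded'", call. = FALSE)
  }
  structure(
    list(loaded = loaded, bound = bound, unbound = loaded - bound,
         efficiency = 100 * bound / loaded),
    class = "mass_balance"
  )
}

#' @export
print.mass_balance <- function(x, ...) {
  cat(sprintf(
    "Mass balance: %.2f ug loaded, %.2f ug bound (%.2f%%), %.2f ug unbound\n",
    x$loaded, x$bound, x$efficiency, x$unbound))
  invisible(x)
}
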