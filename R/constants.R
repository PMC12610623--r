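#' Physical constants and default experimental conditions
#'
#' `kB` is the CODATA Boltzmann constant. Default solvent conditions are
#' water at 25 degrees C (298.15 K, dynamic viscosity 0.89 cP), the
#' conditions under which the FCS measurements and the Stokes-Einstein
#' conversion are defined. Molecular-weight defaults cover Cas9 (about
#' 160 kDa), a 100-nt single-guide RNA (about 32 kDa) and their 1:1 RNP
#' complex; they are conventional round figures and every function taking a
#' molecular weight accepts an override.
#'
#' @format Named numeric constants (SI units unless stated).
#' @name rnpquant-constants
NULL

#' @rdname rnpquant-constants
#' @export
kB <- 1.380649e-23 # J / K

#' @rdname rnpquant-constants
#' @export
DEFAULT_TEMPERATURE <- 298.15 # K

#' @rdname rnpquant-constants
#' @export
DEFAULT_VISCOSITY <- 0.89e-3 # Pa s (0.89 cP, water at 25 C)

#' @rdname rnpquant-constants
#' @export
MW_CAS9 <- 160e3 # g / mol

#' @rdname rnpquant-constants
#' @export
MW_SGRNA_100NT <- 32e3 # g / mol

#' @rdname rnpquant-constants
#' @export
MW_RNP <- MW_CAS9 + MW_SGRNA_100NT # g / mol, 1:1 complex
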