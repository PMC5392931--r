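#' Physical and physiological constants used throughout the package
#'
#' Single versioned registry of the constants behind every computation:
#' thermodynamic constants, the acid dissociation exponent of the
#' ammonium/ammonia pair, and the biomass-specific parameters of the
#' transport and yield models.
#'
#' All concentrations in this package are carried in mmol/L, which is
#' numerically identical to mol/m^3; this makes the flux equation
#' `q_N = 1000 * P * a_m * dC` unit-coherent with `P` in m/h, `a_m` in
#' m^2/g_CDW and `q_N` in mmol/g_CDW/h.
#'
#' @return Named list:
#' \describe{
#'   \item{gas_constant}{J/mol/K.}
#'   \item{faraday}{C/mol.}
#'   \item{pKa_ammonium}{Acid dissociation exponent of NH4+/NH3 (9.25,
#'     used uncorrected at 30 degrees C).}
#'   \item{temperature}{Default cultivation temperature, K (303.15 = 30 C).}
#'   \item{glucose_molar_mass}{g/mmol (0.18016), used for biomass yields.}
#'   \item{membrane_area}{Biomass-specific membrane area a_m, m^2/g_CDW.}
#'   \item{biomass_n_content}{Nitrogen content of biomass chi_N,
#'     mol N/g_CDW.}
#'   \item{registry_version}{Version string of this registry.}
#' }
#' @examples
#' ammoflux_constants()$pKa_ammonium
#' @export
ammoflux_constants <- function() {
  list(
    gas_constant       = 8.314462618,  # J/mol/K
    faraday            = 96485.33212,  # C/mol
    pKa_ammonium       = 9.25,
    temperature        = 303.15,       # K
    glucose_molar_mass = 0.18016,      # g/mmol
    membrane_area      = 3.22,         # m^2/g_CDW
    biomass_n_content  = 5.60e-3,      # mol N/g_CDW
    registry_version   = "1.0"
  )
}

# internal: stop with a clean, call-free message
abort <- function(fmt, ..., class = "ammoflux_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ammoflux_error")))
}

check_scalar_pH <- function(pH, what = "pH") {
  if (!is.numeric(pH) || any(!is.finite(pH)) || any(pH <= 0) || any(pH >= 14)) {
    bad <- pH[!is.finite(pH) | pH <= 0 | pH >= 14][1]
    abort("%s out of the open interval (0, 14): %s", what, format(bad),
          class = "ammoflux_domain_error")
  }
  invisible(pH)
}

check_nonnegative <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    bad <- x[!is.finite(x) | x < 0][1]
    abort("%s must be non-negative, got %s", what, format(bad),
          class = "ammoflux_domain_error")
  }
  invisible(x)
}
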