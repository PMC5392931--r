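#' Acid-base parameters of the ammonium/ammonia pair
#'
#' @param pKa Acid dissociation exponent (dimensionless). Default 9.25, the
#'   value governing NH4+/NH3 partitioning; no implicit temperature
#'   correction is applied.
#' @param temperature Absolute temperature in kelvin, used wherever the
#'   Nernst slope enters (default 303.15 K, i.e. 30 degrees C).
#' @return Object of class `acid_base_params`.
#' @examples
#' acid_base_params()
#' @export
acid_base_params <- function(pKa = 9.25, temperature = 303.15) {
  if (!is.numeric(pKa) || length(pKa) != 1L || !is.finite(pKa) ||
      pKa <= 0 || pKa >= 14) {
    abort("pKa must lie in (0, 14), got %s", format(pKa),
          class = "ammoflux_domain_error")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    abort("temperature must be positive (kelvin), got %s", format(temperature),
          class = "ammoflux_domain_error")
  }
  structure(list(pKa = pKa, temperature = temperature),
            class = "acid_base_params")
}

#' @export
print.acid_base_params <- function(x, ...) {
  cat(sprintf("<acid_base_params> pKa = %g, T = %g K\n", x$pKa, x$temperature))
  invisible(x)
}

#' Mole fraction of free NH3 in the total ammonium pool
#'
#' Henderson-Hasselbalch partitioning: `f = 1 / (1 + 10^(pKa - pH))`.
#' Below the pKa almost all of the pool is the charged species NH4+; the
#' ratio NH3/NH4+ equals `10^(pH - pKa)`.
#'
#' @param pH Solution pH (vectorised), must lie in (0, 14).
#' @param params [acid_base_params()].
#' @return NH3 mole fraction in `[0, 1]`, strictly increasing in pH.
#' @examples
#' nh3_fraction(7)                     # ~ 10^(7 - 9.25)
#' nh3_fraction(9.25)                  # exactly 0.5 at pH = pKa
#' @export
nh3_fraction <- function(pH, params = acid_base_params()) {
  stopifnot(inherits(params, "acid_base_params"))
  check_scalar_pH(pH)
  1 / (1 + 10^(params$pKa - pH))
}

#' Partition a total NH_X concentration into NH3 and NH4+
#'
#' @param total_nhx Total pool (NH3 + NH4+), mmol/L, non-negative.
#' @param pH Solution pH in (0, 14).
#' @param params [acid_base_params()].
#' @return data.frame with columns `nh3` and `nh4` (mmol/L). The two
#'   columns sum to `total_nhx` exactly.
#' @examples
#' speciate(2.61, 6)   # NH3 ~ 1.47e-3 mmol/L (1.47 umol/L)
#' @export
speciate <- function(total_nhx, pH, params = acid_base_params()) {
  check_nonnegative(total_nhx, "total NH_X concentration")
  f <- nh3_fraction(pH, params)
  nh3 <- total_nhx * f
  data.frame(nh3 = nh3, nh4 = total_nhx - nh3)
}

#' Nernst slope
#'
#' The millivolt equivalent of one pH unit (or one decade of ion
#' accumulation): `Z = ln(10) * R * T / F`, in mV.
#'
#' @param temperature Kelvin, positive (vectorised).
#' @return Z in millivolt; ~60.15 mV at 303.15 K.
#' @examples
#' nernst_slope(303.15)
#' @export
nernst_slope <- function(temperature = 303.15) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    abort("temperature must be positive (kelvin)",
          class = "ammoflux_domain_error")
  }
  k <- ammoflux_constants()
  log(10) * k$gas_constant * temperature / k$faraday * 1000
}
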