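#' Predicted IC/EC NH_X ratio under passive NH3 diffusion
#'
#' At steady state with pure NH3 diffusion the free NH3 concentration in
#' the cytosol equilibrates with the extracellular one, so the whole-cell
#' to extracellular NH_X ratio depends only on the speciation inside and
#' outside:
#' `IC/EC = retention_factor(model) / (1 + 10^(pKa - pH_EC))`.
#' The ratio is independent of the absolute concentration level and rises
#' tenfold per unit of extracellular pH while `pKa - pH_EC >= 2`.
#'
#' @param pH_EC Extracellular pH in (0, 14).
#' @param model [cell_model()].
#' @return Dimensionless predicted ratio.
#' @examples
#' predicted_ratio_diffusion(6)  # default model
#' @export
predicted_ratio_diffusion <- function(pH_EC, model = cell_model()) {
  check_scalar_pH(pH_EC, "extracellular pH")
  retention_factor(model) / (1 + 10^(model$acid_base$pKa - pH_EC))
}

#' Predicted IC/EC NH_X ratio under NH4+ uniport
#'
#' An electrogenic NH4+ uniporter equilibrates the ammonium ion with the
#' membrane potential: `[NH4+]_cyt / [NH4+]_EC = 10^(-delta_psi / Z)` with
#' `delta_psi = pmf + Z * (pH_cyt - pH_EC)` (negative inside). Converting
#' cytosolic NH4+ to free NH3 and aggregating over compartments gives
#' `IC/EC = 10^(-delta_psi/Z) * 10^(pH_cyt - pKa) * retention_factor(model)
#'          / (1 + 10^(pH_EC - pKa))`.
#' With constant pmf the cytosolic-pH terms cancel except through the
#' retention factor, and the ratio rises tenfold per unit of extracellular
#' pH.
#'
#' @param pH_EC Extracellular pH in (0, 14).
#' @param model [cell_model()]; must contain a compartment named
#'   `"cytosol"`.
#' @param energetics [membrane_energetics()].
#' @return Dimensionless predicted ratio (> 0).
#' @examples
#' predicted_ratio_uniport(5)
#' @export
predicted_ratio_uniport <- function(pH_EC, model = cell_model(),
                                    energetics = membrane_energetics()) {
  check_scalar_pH(pH_EC, "extracellular pH")
  stopifnot(inherits(energetics, "membrane_energetics"))
  pH_cyt <- compartment_pH(model, "cytosol")
  pKa <- model$acid_base$pKa
  Z <- energetics$Z
  delta_psi <- energetics$pmf + Z * (pH_cyt - pH_EC)
  10^(-delta_psi / Z) * 10^(pH_cyt - pKa) * retention_factor(model) /
    (1 + 10^(pH_EC - pKa))
}

#' Sensitivity bounds on the predicted IC/EC ratio
#'
#' Minimum and maximum of the mechanism-specific predicted ratio over a
#' [sensitivity_box()] of vacuolar volume fraction, cytosolic pH and
#' vacuolar pH. Both predicted ratios are monotone in each box coordinate,
#' so the extremes are attained on corners; the eight corners are evaluated
#' directly. When several corners tie, the lexicographically first
#' combination in (vacuole fraction, cytosol pH, vacuole pH) order is
#' reported.
#'
#' @param mechanism `"diffusion"` or `"uniport"`.
#' @param pH_EC Extracellular pH in (0, 14).
#' @param box [sensitivity_box()].
#' @param base_model [cell_model()] providing the non-varied compartments.
#' @param energetics [membrane_energetics()] (uniport only).
#' @return List with elements `min`, `max` (dimensionless), `nominal` (the
#'   ratio of the unmodified `base_model`), and `min_corner`/`max_corner`
#'   (named numeric vectors of the attaining parameter combinations).
#' @examples
#' ratio_bounds("diffusion", 5)  # (0.051, 2.57) for the default box
#' @export
ratio_bounds <- function(mechanism = c("diffusion", "uniport"), pH_EC,
                         box = sensitivity_box(), base_model = cell_model(),
                         energetics = membrane_energetics()) {
  mechanism <- match.arg(mechanism)
  check_scalar_pH(pH_EC, "extracellular pH")
  stopifnot(inherits(box, "sensitivity_box"))

  # lexicographic corner order (V_vac, pH_cyt, pH_vac) for tie-breaking
  corners <- expand.grid(vacuole_pH = unique(box$vacuole_pH),
                         cytosol_pH = unique(box$cytosol_pH),
                         vacuole_fraction = unique(box$vacuole_fraction),
                         KEEP.OUT.ATTRS = FALSE)
  corners <- corners[, c("vacuole_fraction", "cytosol_pH", "vacuole_pH")]
  corners <- corners[order(corners$vacuole_fraction, corners$cytosol_pH,
                           corners$vacuole_pH), , drop = FALSE]

  eval_point <- function(vf, pc, pv) {
    m <- set_compartment(base_model, "vacuole", volume_fraction = vf, pH = pv)
    m <- set_compartment(m, "cytosol", pH = pc)
    switch(mechanism,
           diffusion = predicted_ratio_diffusion(pH_EC, m),
           uniport   = predicted_ratio_uniport(pH_EC, m, energetics))
  }
  vals <- mapply(eval_point, corners$vacuole_fraction, corners$cytosol_pH,
                 corners$vacuole_pH)
  i_min <- which.min(vals)
  i_max <- which.max(vals)
  nominal <- switch(mechanism,
                    diffusion = predicted_ratio_diffusion(pH_EC, base_model),
                    uniport   = predicted_ratio_uniport(pH_EC, base_model,
                                                        energetics))
  as_corner <- function(i) {
    c(vacuole_fraction = corners$vacuole_fraction[i],
      cytosol_pH = corners$cytosol_pH[i],
      vacuole_pH = corners$vacuole_pH[i])
  }
  list(min = vals[i_min], max = vals[i_max], nominal = nominal,
       min_corner = as_corner(i_min), max_corner = as_corner(i_max))
}

#' Classify the transport mechanism from a measured IC/EC ratio
#'
#' Compares a measured whole-cell/extracellular NH_X ratio with the
#' sensitivity bounds predicted for passive NH3 diffusion and for NH4+
#' uniport. The two bound intervals are separated by more than an order of
#' magnitude at physiological pH, which is what makes the measurement
#' discriminating.
#'
#' @param measured_ratio Measured IC/EC ratio (> 0).
#' @param pH_EC Extracellular pH.
#' @param box,base_model,energetics Passed to [ratio_bounds()].
#' @return `"diffusion"`, `"uniport"`, or `"ambiguous"` when the ratio
#'   falls in neither interval (or, for a degenerate box, in both).
#' @examples
#' classify_mechanism(4.2, 6)    # diffusion regime
#' classify_mechanism(219, 5)    # uniport regime
#' @export
classify_mechanism <- function(measured_ratio, pH_EC,
                               box = sensitivity_box(),
                               base_model = cell_model(),
                               energetics = membrane_energetics()) {
  check_nonnegative(measured_ratio, "measured ratio")
  d <- ratio_bounds("diffusion", pH_EC, box, base_model, energetics)
  u <- ratio_bounds("uniport", pH_EC, box, base_model, energetics)
  in_d <- measured_ratio >= d$min && measured_ratio <= d$max
  in_u <- measured_ratio >= u$min && measured_ratio <= u$max
  if (in_d && !in_u) "diffusion" else if (in_u && !in_d) "uniport"
  else "ambiguous"
}
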