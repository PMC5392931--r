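#' Define a cellular compartment
#'
#' @param name Compartment identifier (unique within a model).
#' @param volume_fraction Fraction of the total cell volume (including dry
#'   matter) occupied by the compartment, in (0, 1].
#' @param pH Compartment pH in (0, 14).
#' @return Object of class `compartment`.
#' @examples
#' compartment("vacuole", 0.14, 4.5)
#' @export
compartment <- function(name, volume_fraction, pH) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("compartment name must be a non-empty string")
  }
  if (!is.numeric(volume_fraction) || length(volume_fraction) != 1L ||
      !is.finite(volume_fraction) ||
      volume_fraction <= 0 || volume_fraction > 1) {
    abort("volume_fraction of '%s' must lie in (0, 1], got %s",
          name, format(volume_fraction), class = "ammoflux_domain_error")
  }
  check_scalar_pH(pH, sprintf("pH of compartment '%s'", name))
  structure(list(name = name, volume_fraction = volume_fraction, pH = pH),
            class = "compartment")
}

#' Multi-compartment cell model
#'
#' Describes the intracellular volume as a set of pH-homogeneous
#' compartments. The default is the three-compartment yeast model used for
#' all whole-cell deconvolutions: cytosol (70% of cell volume, pH 6.5),
#' vacuole (14%, pH 4.5) and mitochondria (1%, pH 7.5). The remaining cell
#' volume (dry matter and minor organelles) is assumed NH_X-free.
#'
#' The cytosolic pH default of 6.5 is the midpoint of the 6-7 sensitivity
#' range; the mitochondrial pH (not critical, contributing <0.01% of the
#' retention factor) defaults to 7.5 and is configurable.
#'
#' @param compartments List of [compartment()] objects with unique names;
#'   volume fractions must sum to at most 1.
#' @param acid_base [acid_base_params()].
#' @return Object of class `cell_model` with elements `compartments`
#'   (data.frame: name, volume_fraction, pH) and `acid_base`.
#' @examples
#' cell_model()
#' @export
cell_model <- function(compartments = list(
                         compartment("cytosol",      0.70, 6.5),
                         compartment("vacuole",      0.14, 4.5),
                         compartment("mitochondria", 0.01, 7.5)),
                       acid_base = acid_base_params()) {
  if (length(compartments) == 0L) {
    abort("a cell model needs at least one compartment",
          class = "ammoflux_domain_error")
  }
  if (inherits(compartments, "compartment")) compartments <- list(compartments)
  stopifnot(all(vapply(compartments, inherits, TRUE, "compartment")),
            inherits(acid_base, "acid_base_params"))
  comp <- data.frame(
    name            = vapply(compartments, `[[`, "", "name"),
    volume_fraction = vapply(compartments, `[[`, 0, "volume_fraction"),
    pH              = vapply(compartments, `[[`, 0, "pH"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(comp$name)) {
    abort("compartment names must be unique: %s",
          paste(comp$name[duplicated(comp$name)], collapse = ", "))
  }
  if (sum(comp$volume_fraction) > 1 + 1e-12) {
    abort("compartment volume fractions sum to %.3f > 1",
          sum(comp$volume_fraction), class = "ammoflux_domain_error")
  }
  structure(list(compartments = comp, acid_base = acid_base),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> pKa = %g\n", x$acid_base$pKa))
  print(x$compartments, row.names = FALSE)
  invisible(x)
}

# internal: replace fields of one named compartment, returning a new model
set_compartment <- function(model, name, volume_fraction = NULL, pH = NULL) {
  comp <- model$compartments
  i <- match(name, comp$name)
  if (is.na(i)) {
    abort("cell model has no compartment named '%s'", name,
          class = "ammoflux_config_error")
  }
  if (!is.null(volume_fraction)) comp$volume_fraction[i] <- volume_fraction
  if (!is.null(pH)) comp$pH[i] <- pH
  cell_model(
    compartments = lapply(seq_len(nrow(comp)), function(j) {
      compartment(comp$name[j], comp$volume_fraction[j], comp$pH[j])
    }),
    acid_base = model$acid_base
  )
}

# internal: pH of a named compartment (error if absent)
compartment_pH <- function(model, name) {
  i <- match(name, model$compartments$name)
  if (is.na(i)) {
    abort("cell model has no compartment named '%s'", name,
          class = "ammoflux_config_error")
  }
  model$compartments$pH[i]
}

#' Sensitivity box for the compartment model
#'
#' Parameter ranges explored when bounding predicted IC/EC ratios and when
#' searching for a feasible steady-state deconvolution: vacuolar volume
#' fraction, cytosolic pH and vacuolar pH. Defaults are the ranges used for
#' the published sensitivity analysis.
#'
#' @param vacuole_fraction Length-2 numeric, `c(lo, hi)` in (0, 1].
#' @param cytosol_pH Length-2 numeric range in (0, 14).
#' @param vacuole_pH Length-2 numeric range in (0, 14).
#' @return Object of class `sensitivity_box`.
#' @examples
#' sensitivity_box()
#' @export
sensitivity_box <- function(vacuole_fraction = c(0.14, 0.25),
                            cytosol_pH = c(6.0, 7.0),
                            vacuole_pH = c(4.0, 5.5)) {
  chk <- function(r, what, lo, hi) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) ||
        r[1] > r[2] || r[1] <= lo || r[2] >= hi) {
      abort("%s must be an ordered range inside (%g, %g)", what, lo, hi,
            class = "ammoflux_domain_error")
    }
  }
  chk(vacuole_fraction, "vacuole_fraction", 0, 1 + 1e-12)
  chk(cytosol_pH, "cytosol_pH", 0, 14)
  chk(vacuole_pH, "vacuole_pH", 0, 14)
  structure(list(vacuole_fraction = vacuole_fraction,
                 cytosol_pH = cytosol_pH,
                 vacuole_pH = vacuole_pH),
            class = "sensitivity_box")
}

#' Plasma-membrane energetics for the uniport model
#'
#' Holds the proton motive force and the Nernst slope from which the
#' membrane potential is derived at a given pH gradient:
#' `delta_psi = pmf + Z * (pH_cyt - pH_EC)` (negative inside). The default
#' pmf of -200 mV reproduces the published uniport ratio bounds and is a
#' reverse-engineered, configurable default rather than a measured value.
#'
#' @param pmf Proton motive force in mV, negative inside (default -200).
#' @param temperature Kelvin, used for the Nernst slope Z.
#' @return Object of class `membrane_energetics` with elements `pmf` and
#'   `Z` (mV).
#' @examples
#' membrane_energetics()
#' @export
membrane_energetics <- function(pmf = -200, temperature = 303.15) {
  if (!is.numeric(pmf) || length(pmf) != 1L || !is.finite(pmf) || pmf >= 0) {
    abort("pmf must be negative (mV, negative inside), got %s", format(pmf),
          class = "ammoflux_domain_error")
  }
  structure(list(pmf = pmf, Z = nernst_slope(temperature)),
            class = "membrane_energetics")
}

#' NH_X retention factor of a cell model
#'
#' With free NH3 equilibrated across all compartments (passive NH3
#' diffusion between organelles), each compartment holds
#' `NH3 * (1 + 10^(pKa - pH_i))` total NH_X, so the whole-cell NH_X
#' concentration per litre of cell equals the free NH3 concentration times
#' the volume-weighted sum `sum(V_i * (1 + 10^(pKa - pH_i)))` -- the
#' retention factor. Acidic compartments (the vacuole) dominate it because
#' they trap inward-diffusing NH3 as NH4+.
#'
#' @param model [cell_model()].
#' @return Dimensionless factor `>= sum(V_i)`, strictly decreasing in every
#'   compartment pH.
#' @examples
#' retention_factor(cell_model())  # ~ 8.27e3 for the default model
#' @export
retention_factor <- function(model) {
  stopifnot(inherits(model, "cell_model"))
  comp <- model$compartments
  sum(comp$volume_fraction * (1 + 10^(model$acid_base$pKa - comp$pH)))
}

#' Free cytosolic NH3 from a whole-cell NH_X measurement
#'
#' Inverts the compartmental equilibrium: metabolomics measures the
#' whole-cell ("intracellular") NH_X pool, and the free NH3 concentration
#' common to all compartments is that measurement divided by the
#' [retention_factor()].
#'
#' @param wholecell_nhx Whole-cell NH_X, mmol per litre of cell volume
#'   (non-negative, vectorised).
#' @param model [cell_model()].
#' @return Free NH3 concentration, mmol/L.
#' @examples
#' free_nh3_from_wholecell(10.9, cell_model()) * 1e3  # ~1.32 umol/L
#' @export
free_nh3_from_wholecell <- function(wholecell_nhx, model = cell_model()) {
  check_nonnegative(wholecell_nhx, "whole-cell NH_X")
  wholecell_nhx / retention_factor(model)
}

#' Whole-cell NH_X implied by a free NH3 concentration
#'
#' Forward direction of [free_nh3_from_wholecell()]; the two round-trip to
#' machine precision.
#'
#' @param nh3_free Free NH3, mmol/L (non-negative, vectorised).
#' @param model [cell_model()].
#' @return Whole-cell NH_X, mmol per litre of cell volume.
#' @export
wholecell_from_free_nh3 <- function(nh3_free, model = cell_model()) {
  check_nonnegative(nh3_free, "free NH3")
  nh3_free * retention_factor(model)
}

#' Per-compartment NH3/NH4+/NH_X profile at a given free NH3 level
#'
#' @param nh3_free Free NH3 concentration, mmol/L (scalar, non-negative).
#' @param model [cell_model()].
#' @return data.frame with one row per compartment: `name`,
#'   `volume_fraction`, `pH`, `nh3`, `nh4`, `nhx` (all concentrations in
#'   mmol/L). NH3 is identical in all compartments;
#'   `NH4_i = NH3 * 10^(pKa - pH_i)`. The volume-weighted `nhx` total
#'   equals [wholecell_from_free_nh3()].
#' @examples
#' compartment_profile(1e-3, cell_model())  # vacuolar NH4+ ~ 56 mmol/L
#' @export
compartment_profile <- function(nh3_free, model = cell_model()) {
  check_nonnegative(nh3_free, "free NH3")
  stopifnot(length(nh3_free) == 1L, inherits(model, "cell_model"))
  comp <- model$compartments
  nh4 <- nh3_free * 10^(model$acid_base$pKa - comp$pH)
  data.frame(name = comp$name,
             volume_fraction = comp$volume_fraction,
             pH = comp$pH,
             nh3 = rep(nh3_free, nrow(comp)),
             nh4 = nh4,
             nhx = nh3_free + nh4,
             stringsAsFactors = FALSE)
}
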