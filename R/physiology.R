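#' ATP stoichiometry of respirofermentative metabolism
#'
#' @param atp_per_o2 mol ATP per mol O2 respired (default 1.9, the
#'   effective P/O-derived yield under aerobic N-limitation).
#' @param atp_per_ethanol mol ATP per mol ethanol formed by alcoholic
#'   fermentation (default 1).
#' @return Object of class `atp_stoichiometry`.
#' @export
atp_stoichiometry <- function(atp_per_o2 = 1.9, atp_per_ethanol = 1) {
  check_nonnegative(atp_per_o2, "atp_per_o2")
  check_nonnegative(atp_per_ethanol, "atp_per_ethanol")
  structure(list(atp_per_o2 = atp_per_o2, atp_per_ethanol = atp_per_ethanol),
            class = "atp_stoichiometry")
}

#' ATP production rate from oxygen and ethanol rates
#'
#' `q_ATP = atp_per_o2 * q_O2 + atp_per_ethanol * q_EtOH`, all rates as
#' non-negative magnitudes in mmol/g_CDW/h.
#'
#' @param q_o2 Oxygen consumption rate magnitude, mmol/g_CDW/h.
#' @param q_etoh Ethanol production rate magnitude, mmol/g_CDW/h.
#' @param stoich [atp_stoichiometry()].
#' @return ATP production rate, mmol/g_CDW/h (vectorised).
#' @examples
#' atp_rate(1.643, 4.601)  # 7.72
#' @export
atp_rate <- function(q_o2, q_etoh, stoich = atp_stoichiometry()) {
  check_nonnegative(q_o2, "q_O2")
  check_nonnegative(q_etoh, "q_EtOH")
  stopifnot(inherits(stoich, "atp_stoichiometry"))
  stoich$atp_per_o2 * q_o2 + stoich$atp_per_ethanol * q_etoh
}

#' Derived physiology of chemostat steady states
#'
#' Recomputes the derived columns of a chemostat rate table from its
#' measured columns:
#' biomass yield `Y_XS = mu / (q_S * M_glucose)` (g_CDW/g glucose, with
#' M_glucose = 0.18016 g/mmol), carbon-to-nitrogen consumption ratio
#' `C/N = 6 * q_S / q_N` (glucose carbon only), ATP production rate
#' [atp_rate()], and the ATP cost per assimilated nitrogen
#' `q_ATP / q_N` (mol ATP/mol N).
#'
#' @param obs data.frame of observations with columns `mu`, `q_s`, `q_o2`,
#'   `q_etoh`, `q_n` (rates as non-negative magnitudes, mmol/g_CDW/h;
#'   `mu` in 1/h); `strain` and `ph_ec` are carried through when present.
#'   Typically from [read_observations()].
#' @param stoich [atp_stoichiometry()].
#' @return data.frame with columns `strain`, `ph_ec`, `y_xs`, `cn_ratio`,
#'   `q_atp`, `qatp_per_qn`.
#' @examples
#' obs <- data.frame(mu = 0.053, q_s = 3.862, q_o2 = 1.643,
#'                   q_etoh = 4.601, q_n = 0.251)
#' physiology_summary(obs)
#' @export
physiology_summary <- function(obs, stoich = atp_stoichiometry()) {
  obs <- as.data.frame(obs)
  for (f in c("mu", "q_s", "q_o2", "q_etoh", "q_n")) {
    if (is.null(obs[[f]])) {
      abort("observations are missing column '%s'", f,
            class = "ammoflux_config_error")
    }
  }
  if (any(obs$q_s <= 0)) {
    abort("q_s must be positive to compute yields",
          class = "ammoflux_domain_error")
  }
  if (any(obs$q_n <= 0)) {
    abort("q_n must be positive to compute per-nitrogen quantities",
          class = "ammoflux_domain_error")
  }
  m_glc <- ammoflux_constants()$glucose_molar_mass
  q_atp <- atp_rate(obs$q_o2, obs$q_etoh, stoich)
  data.frame(
    strain = if (is.null(obs$strain)) NA_character_ else obs$strain,
    ph_ec = if (is.null(obs$ph_ec)) NA_real_ else obs$ph_ec,
    y_xs = obs$mu / (obs$q_s * m_glc),
    cn_ratio = 6 * obs$q_s / obs$q_n,
    q_atp = q_atp,
    qatp_per_qn = q_atp / obs$q_n,
    stringsAsFactors = FALSE
  )
}

#' Cellular concentration from a biomass-specific content
#'
#' `concentration = content / cell_volume`; with content in umol/g_CDW and
#' the average cell volume (including dry matter) in mL/g_CDW the result is
#' in mmol/L of cell volume (umol/mL = mmol/L).
#'
#' @param content Metabolite content, umol/g_CDW (non-negative,
#'   vectorised).
#' @param cell_volume Average cell volume, mL/g_CDW (> 0).
#' @return Cellular concentration, mmol/L.
#' @examples
#' cellular_concentration(21.8, 2.00)  # 10.9 mmol/L
#' @export
cellular_concentration <- function(content, cell_volume) {
  check_nonnegative(content, "content")
  if (any(!is.finite(cell_volume)) || any(cell_volume <= 0)) {
    abort("cell_volume must be positive (mL/g_CDW)",
          class = "ammoflux_domain_error")
  }
  content / cell_volume
}

#' Measured whole-cell to extracellular NH_X ratio
#'
#' @param nhx_ic Whole-cell NH_X, mmol/L of cell volume.
#' @param nhx_ec Extracellular NH_X, mmol/L (> 0).
#' @return Dimensionless IC/EC ratio (vectorised).
#' @examples
#' measured_ic_ec_ratio(7.48, 0.57)  # ~13.1
#' @export
measured_ic_ec_ratio <- function(nhx_ic, nhx_ec) {
  check_nonnegative(nhx_ic, "whole-cell NH_X")
  if (any(!is.finite(nhx_ec)) || any(nhx_ec <= 0)) {
    abort("extracellular NH_X must be positive",
          class = "ammoflux_domain_error")
  }
  nhx_ic / nhx_ec
}

#' Internal-consistency checks of a chemostat rate table
#'
#' Report-only validation. For every row, checks the nitrogen balance
#' `q_N = mu * n_content` (at steady state the nitrogen taken up ends up in
#' biomass) and, when a table of previously reported derived columns is
#' supplied, compares them with the values recomputed by
#' [physiology_summary()]. Nothing is mutated; rows deviating beyond the
#' tolerance are flagged.
#'
#' @param obs data.frame of observations (columns as in
#'   [physiology_summary()] plus `n_content` in mmol N/g_CDW for the
#'   nitrogen balance).
#' @param derived Optional data.frame of reported derived values with any
#'   of the columns `y_xs`, `cn_ratio`, `q_atp`, `qatp_per_qn`, row-aligned
#'   with `obs`.
#' @param tolerance Relative tolerance for flagging (default 0.02).
#' @param stoich [atp_stoichiometry()].
#' @return data.frame report of the flagged checks, with columns `row`,
#'   `strain`, `ph_ec`, `check`, `reported`, `recomputed`, `rel_dev`;
#'   zero rows when every check passes.
#' @examples
#' obs <- data.frame(strain = "IME169", ph_ec = 5, mu = 0.053,
#'                   q_s = 3.862, q_o2 = 1.643, q_etoh = 4.601,
#'                   q_n = 0.251, n_content = 4.70)
#' validate_observation(obs)
#' @export
validate_observation <- function(obs, derived = NULL, tolerance = 0.02,
                                 stoich = atp_stoichiometry()) {
  obs <- as.data.frame(obs)
  check_nonnegative(tolerance, "tolerance")
  n <- nrow(obs)
  rows <- list()
  add <- function(row, check, reported, recomputed) {
    rel <- abs(recomputed / reported - 1)
    rows[[length(rows) + 1L]] <<- data.frame(
      row = row,
      strain = if (is.null(obs$strain)) NA_character_ else obs$strain[row],
      ph_ec = if (is.null(obs$ph_ec)) NA_real_ else obs$ph_ec[row],
      check = check, reported = reported, recomputed = recomputed,
      rel_dev = rel, flagged = rel > tolerance,
      stringsAsFactors = FALSE)
  }
  if (!is.null(obs$n_content) && !is.null(obs$q_n) && !is.null(obs$mu)) {
    for (i in seq_len(n)) {
      add(i, "nitrogen_balance", obs$q_n[i], obs$mu[i] * obs$n_content[i])
    }
  }
  if (!is.null(derived)) {
    derived <- as.data.frame(derived)
    stopifnot(nrow(derived) == n)
    recomputed <- physiology_summary(obs, stoich)
    for (col in intersect(c("y_xs", "cn_ratio", "q_atp", "qatp_per_qn"),
                          names(derived))) {
      for (i in seq_len(n)) add(i, col, derived[[col]][i], recomputed[[col]][i])
    }
  }
  empty <- data.frame(row = integer(0), strain = character(0),
                      ph_ec = numeric(0), check = character(0),
                      reported = numeric(0), recomputed = numeric(0),
                      rel_dev = numeric(0), stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(empty)
  report <- do.call(rbind, rows)
  report <- report[report$flagged, setdiff(names(report), "flagged"),
                   drop = FALSE]
  if (nrow(report) == 0L) empty else `rownames<-`(report, NULL)
}
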