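# CSV schema of chemostat observation tables; units embedded in the
# column names to prevent silent unit drift.
obs_schema <- c(strain = "strain", pH_EC = "ph_ec", mu_1ph = "mu",
                qS_mmolgh = "q_s", qO2_mmolgh = "q_o2",
                qCO2_mmolgh = "q_co2", qEtOH_mmolgh = "q_etoh",
                qN_mmolgh = "q_n", Ncontent_mmolg = "n_content",
                biomass_gL = "biomass", cellvol_mLg = "cell_volume",
                NHX_IC_mM = "nhx_ic", NHX_EC_mM = "nhx_ec")

#' Read a chemostat observation table
#'
#' Reads the fixed comma-separated schema
#' `strain,pH_EC,mu_1ph,qS_mmolgh,qO2_mmolgh,qCO2_mmolgh,qEtOH_mmolgh,`
#' `qN_mmolgh,Ncontent_mmolg,biomass_gL,cellvol_mLg,NHX_IC_mM,NHX_EC_mM`
#' (dot decimal, UTF-8, header required) into a validated data.frame with
#' the package-internal column names (`strain`, `ph_ec`, `mu`, `q_s`,
#' `q_o2`, `q_co2`, `q_etoh`, `q_n`, `n_content`, `biomass`,
#' `cell_volume`, `nhx_ic`, `nhx_ec`). All offending cells are reported at
#' once, with row numbers.
#'
#' A fixture with the six published strain x pH steady states ships with
#' the package: `system.file("extdata", "chemostat_observations.csv",
#' package = "ammoflux")`.
#'
#' @param path Path to the CSV file.
#' @return data.frame, one row per steady state (possibly zero rows).
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) {
    abort("observations file not found: %s", path,
          class = "ammoflux_parse_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(names(obs_schema), names(raw))
  if (length(missing_cols)) {
    abort("missing column(s): %s", paste(missing_cols, collapse = ", "),
          class = "ammoflux_parse_error")
  }
  raw <- raw[names(obs_schema)]
  names(raw) <- unname(obs_schema)
  problems <- character(0)
  numeric_cols <- setdiff(names(raw), "strain")
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & nzchar(trimws(raw[[col]])))
    for (r in bad) {
      problems <- c(problems, sprintf("row %d, %s: non-numeric '%s'",
                                      r, col, raw[[col]][r]))
    }
    raw[[col]] <- val
  }
  check_rule <- function(col, ok, rule) {
    bad <- which(!ok(raw[[col]]) & !is.na(raw[[col]]))
    for (r in bad) {
      problems <<- c(problems, sprintf("row %d, %s: %s (got %g)",
                                       r, col, rule, raw[[col]][r]))
    }
  }
  for (col in c("mu", "q_s", "q_o2", "q_co2", "q_etoh", "q_n", "n_content",
                "biomass", "nhx_ic", "nhx_ec")) {
    check_rule(col, function(x) x >= 0, "must be a non-negative magnitude")
  }
  check_rule("ph_ec", function(x) x > 0 & x < 14, "must lie in (0, 14)")
  check_rule("cell_volume", function(x) x > 0, "must be positive")
  if (length(problems)) {
    abort("invalid observations in %s:\n  %s", path,
          paste(problems, collapse = "\n  "),
          class = "ammoflux_parse_error")
  }
  raw
}

#' Write a chemostat observation table
#'
#' Inverse of [read_observations()]: writes the fixed CSV schema so that a
#' read/write round trip is field-identical.
#'
#' @param obs data.frame with the internal observation columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  obs <- as.data.frame(obs)
  missing_cols <- setdiff(unname(obs_schema), names(obs))
  if (length(missing_cols)) {
    abort("observations are missing column(s): %s",
          paste(missing_cols, collapse = ", "),
          class = "ammoflux_config_error")
  }
  out <- obs[unname(obs_schema)]
  names(out) <- names(obs_schema)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell model from a YAML configuration file
#'
#' Expected layout:
#' ```yaml
#' acid_base:
#'   pKa: 9.25
#'   temperature_K: 303.15
#' compartments:
#'   - name: cytosol
#'     volume_fraction: 0.70
#'     pH: 6.5
#' ```
#' An optional `sensitivity_box` block with `vacuole_fraction`,
#' `cytosol_pH` and `vacuole_pH` two-element ranges is returned alongside.
#'
#' @param path Path to the YAML file.
#' @return List with `model` ([cell_model()]) and `box`
#'   ([sensitivity_box()] or `NULL`).
#' @export
read_cell_model <- function(path) {
  if (!file.exists(path)) {
    abort("cell model file not found: %s", path,
          class = "ammoflux_parse_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$compartments)) {
    abort("%s: no 'compartments' block", path,
          class = "ammoflux_parse_error")
  }
  ab <- cfg$acid_base
  acid_base <- acid_base_params(
    pKa = if (is.null(ab$pKa)) 9.25 else ab$pKa,
    temperature = if (is.null(ab$temperature_K)) 303.15 else ab$temperature_K)
  comps <- lapply(cfg$compartments, function(cc) {
    for (f in c("name", "volume_fraction", "pH")) {
      if (is.null(cc[[f]])) {
        abort("%s: compartment entry missing field '%s'", path, f,
              class = "ammoflux_parse_error")
      }
    }
    compartment(cc$name, cc$volume_fraction, cc$pH)
  })
  box <- NULL
  if (!is.null(cfg$sensitivity_box)) {
    sb <- cfg$sensitivity_box
    box <- sensitivity_box(
      vacuole_fraction = as.numeric(sb$vacuole_fraction),
      cytosol_pH = as.numeric(sb$cytosol_pH),
      vacuole_pH = as.numeric(sb$vacuole_pH))
  }
  list(model = cell_model(comps, acid_base), box = box)
}

#' Run the full steady-state analysis pipeline
#'
#' Executes, for a table of chemostat observations: compartmental
#' deconvolution and permeability estimation ([solve_steady_state()] per
#' row), mechanism-specific IC/EC ratio bounds per extracellular pH
#' ([ratio_bounds()]) together with each row's measured ratio and its
#' classification, physiology summaries ([physiology_summary()]) and the
#' internal-consistency report ([validate_observation()]). Optionally
#' writes one tidy CSV per stage plus a JSON run manifest; outputs are
#' deterministic, so identical inputs give identical files.
#'
#' @param observations Path to an observations CSV or a data.frame with
#'   the internal columns.
#' @param model [cell_model()].
#' @param box [sensitivity_box()].
#' @param params [transport_params()].
#' @param energetics [membrane_energetics()].
#' @param stoich [atp_stoichiometry()].
#' @param out_dir Optional output directory; created if needed.
#' @param seed Optional integer recorded in the manifest and set before
#'   any stage (the deterministic stages ignore it; it pins downstream
#'   simulation work started from the bundle).
#' @return List with `transport`, `ratios`, `physiology`, `validation`
#'   (data.frames) and `manifest` (list).
#' @examples
#' fixture <- system.file("extdata", "chemostat_observations.csv",
#'                        package = "ammoflux")
#' res <- run_pipeline(fixture)
#' res$transport
#' @export
run_pipeline <- function(observations, model = cell_model(),
                         box = sensitivity_box(),
                         params = transport_params(),
                         energetics = membrane_energetics(),
                         stoich = atp_stoichiometry(),
                         out_dir = NULL, seed = NULL) {
  obs <- if (is.character(observations)) {
    read_observations(observations)
  } else {
    as.data.frame(observations)
  }
  if (!is.null(seed)) set.seed(seed)

  transport <- do.call(rbind, lapply(seq_len(nrow(obs)), function(i) {
    as.data.frame(solve_steady_state(obs[i, ], model, params, box))
  }))

  ratios <- do.call(rbind, lapply(seq_len(nrow(obs)), function(i) {
    ph <- obs$ph_ec[i]
    d <- ratio_bounds("diffusion", ph, box, model, energetics)
    u <- ratio_bounds("uniport", ph, box, model, energetics)
    measured <- measured_ic_ec_ratio(obs$nhx_ic[i], obs$nhx_ec[i])
    data.frame(strain = obs$strain[i], pH_EC = ph,
               measured_ratio = measured,
               diffusion_min = d$min, diffusion_max = d$max,
               uniport_min = u$min, uniport_max = u$max,
               classification = classify_mechanism(measured, ph, box,
                                                   model, energetics),
               stringsAsFactors = FALSE)
  }))

  physiology <- physiology_summary(obs, stoich)
  validation <- validate_observation(obs, tolerance = 0.02, stoich = stoich)

  manifest <- list(
    package = "ammoflux",
    package_version = as.character(utils::packageVersion("ammoflux")),
    constants_registry = ammoflux_constants()$registry_version,
    seed = seed,
    n_observations = nrow(obs),
    settings = list(
      pKa = model$acid_base$pKa,
      pmf_mV = energetics$pmf,
      membrane_area_m2_per_g = params$membrane_area,
      atp_per_o2 = stoich$atp_per_o2,
      atp_per_ethanol = stoich$atp_per_ethanol,
      sensitivity_box = unclass(box)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(transport, file.path(out_dir, "transport.csv"),
                     row.names = FALSE)
    utils::write.csv(ratios, file.path(out_dir, "ratio_bounds.csv"),
                     row.names = FALSE)
    utils::write.csv(physiology, file.path(out_dir, "physiology.csv"),
                     row.names = FALSE)
    utils::write.csv(validation, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(transport = transport, ratios = ratios, physiology = physiology,
       validation = validation, manifest = manifest)
}
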