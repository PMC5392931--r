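#' Biomass-specific transport parameters
#'
#' @param membrane_area Biomass-specific membrane area a_m, m^2/g_CDW
#'   (default 3.22).
#' @param n_content Biomass nitrogen content chi_N, mol N/g_CDW (default
#'   5.60e-3), used by the diffusion-limited growth law.
#' @param mu_max Optional ceiling growth rate, 1/h; `NULL` means no
#'   ceiling.
#' @return Object of class `transport_params`.
#' @examples
#' transport_params(mu_max = 0.21)
#' @export
transport_params <- function(membrane_area = 3.22, n_content = 5.60e-3,
                             mu_max = NULL) {
  for (nm in c("membrane_area", "n_content")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort("%s must be a positive scalar", nm,
            class = "ammoflux_domain_error")
    }
  }
  if (!is.null(mu_max) &&
      (!is.numeric(mu_max) || length(mu_max) != 1L || mu_max <= 0)) {
    abort("mu_max must be NULL or a positive scalar",
          class = "ammoflux_domain_error")
  }
  structure(list(membrane_area = membrane_area, n_content = n_content,
                 mu_max = mu_max),
            class = "transport_params")
}

#' Passive NH3 diffusion flux across the plasma membrane
#'
#' `q_N = 1000 * P * a_m * ([NH3]_EC - [NH3]_cyt)` with concentrations in
#' mmol/L (= mol/m^3), `P` in m/h and `a_m` in m^2/g_CDW; the factor 1000
#' is the mol-to-mmol conversion so that the returned uptake rate is in
#' mmol N/g_CDW/h, the unit of the chemostat rate tables.
#'
#' @param permeability Apparent permeability coefficient P, m/h
#'   (non-negative).
#' @param nh3_ec,nh3_cyt Extracellular and cytosolic free NH3, mmol/L.
#' @param params [transport_params()].
#' @return Biomass-specific uptake rate, mmol N/g_CDW/h; positive when the
#'   gradient points inward.
#' @examples
#' diffusion_flux(0.37, 1.47e-3, 1.31e-3)  # ~0.19 mmol/g_CDW/h
#' @export
diffusion_flux <- function(permeability, nh3_ec, nh3_cyt,
                           params = transport_params()) {
  check_nonnegative(permeability, "permeability")
  stopifnot(inherits(params, "transport_params"))
  1000 * permeability * params$membrane_area * (nh3_ec - nh3_cyt)
}

#' Apparent permeability from a measured uptake rate and NH3 gradient
#'
#' Inverse of [diffusion_flux()]:
#' `P = q_N / (1000 * a_m * ([NH3]_EC - [NH3]_cyt))`.
#'
#' @param q_n Uptake rate, mmol N/g_CDW/h (> 0).
#' @param nh3_ec,nh3_cyt Free NH3 concentrations, mmol/L; the gradient
#'   `nh3_ec - nh3_cyt` must be positive.
#' @param params [transport_params()].
#' @return Apparent permeability coefficient, m/h.
#' @examples
#' estimate_permeability(0.183, 1.467e-3, 1.318e-3)  # ~0.38 m/h
#' @export
estimate_permeability <- function(q_n, nh3_ec, nh3_cyt,
                                  params = transport_params()) {
  stopifnot(inherits(params, "transport_params"))
  if (any(q_n <= 0)) {
    abort("q_n must be positive, got %s", format(q_n[q_n <= 0][1]),
          class = "ammoflux_domain_error")
  }
  grad <- nh3_ec - nh3_cyt
  if (any(grad <= 0)) {
    abort(paste("non-positive NH3 gradient (EC %s <= cytosolic %s mmol/L):",
                "no inward diffusion flux is possible under this cell model;",
                "use solve_steady_state(), whose sensitivity-box adjustment",
                "path searches for a feasible compartmentation"),
          format(nh3_ec[grad <= 0][1]), format(nh3_cyt[grad <= 0][1]),
          class = "ammoflux_infeasible_error")
  }
  q_n / (1000 * params$membrane_area * grad)
}

#' Solve one chemostat steady state for cytosolic NH3 and permeability
#'
#' Carries out the full deconvolution for one steady-state observation:
#' extracellular free NH3 by speciation at the culture pH, cytosolic free
#' NH3 by compartmental deconvolution of the whole-cell measurement, and
#' the apparent permeability from the nitrogen uptake rate and the
#' resulting gradient.
#'
#' If the default cell model yields a non-positive gradient (cytosolic NH3
#' at or above the extracellular level), the solver searches the
#' sensitivity box for the least-deviating feasible compartmentation:
#' first the vacuolar volume fraction is raised in 0.01 steps up to the box
#' maximum, then (at the maximum fraction) the vacuolar pH is lowered in
#' 0.1 steps down to the box minimum. A lower vacuolar pH or larger vacuole
#' raises the retention factor, lowering the cytosolic estimate and driving
#' the system toward feasibility. The adjustment, if any, is recorded in
#' the result.
#'
#' @param obs A single observation: one-row data.frame or named list with
#'   at least `ph_ec`, `nhx_ic` (whole-cell NH_X, mmol/L_cell), `nhx_ec`
#'   (extracellular NH_X, mmol/L) and `q_n` (mmol N/g_CDW/h); `strain` is
#'   carried through when present.
#' @param model Default [cell_model()].
#' @param params [transport_params()].
#' @param box [sensitivity_box()] searched on infeasibility.
#' @return Object of class `steady_state_solution`: list with `strain`,
#'   `ph_ec`, `nh3_cyt_umol`, `nh3_ec_umol` (umol/L), `cyt_ec_ratio`,
#'   `permeability` (m/h), `adjusted` (logical), `adjustment` (string or
#'   `NA`), `feasible` (logical) and `model` (the cell model actually
#'   used). An infeasible system (no feasible point anywhere in the box)
#'   returns `feasible = FALSE` with `permeability = NA`, not an error.
#' @examples
#' obs <- list(strain = "IMZ351", ph_ec = 6, nhx_ic = 10.9,
#'             nhx_ec = 2.61, q_n = 0.183)
#' solve_steady_state(obs)
#' @export
solve_steady_state <- function(obs, model = cell_model(),
                               params = transport_params(),
                               box = sensitivity_box()) {
  obs <- as.list(obs)
  for (f in c("ph_ec", "nhx_ic", "nhx_ec", "q_n")) {
    if (is.null(obs[[f]]) || !is.finite(obs[[f]])) {
      abort("observation is missing field '%s'", f,
            class = "ammoflux_config_error")
    }
  }
  nh3_ec <- speciate(obs$nhx_ec, obs$ph_ec, model$acid_base)$nh3

  candidate_models <- function() {
    vac_i <- match("vacuole", model$compartments$name)
    if (is.na(vac_i)) return(list(list(model = model, label = NA_character_)))
    f0 <- model$compartments$volume_fraction[vac_i]
    p0 <- model$compartments$pH[vac_i]
    f_max <- box$vacuole_fraction[2]
    p_min <- box$vacuole_pH[1]
    cands <- list(list(model = model, label = NA_character_))
    fs <- if (f_max > f0 + 1e-9) {
      round(seq(f0 + 0.01, f_max, by = 0.01), 10)
    } else numeric(0)
    for (f in fs) {
      cands[[length(cands) + 1L]] <- list(
        model = set_compartment(model, "vacuole", volume_fraction = f),
        label = sprintf("vacuole volume fraction %.2f (pH %.1f)", f, p0))
    }
    f_top <- if (length(fs)) fs[length(fs)] else f0
    ps <- if (p0 - 0.1 > p_min - 1e-9) {
      round(seq(p0 - 0.1, p_min, by = -0.1), 10)
    } else numeric(0)
    for (p in ps) {
      cands[[length(cands) + 1L]] <- list(
        model = set_compartment(model, "vacuole", volume_fraction = f_top,
                                pH = p),
        label = sprintf("vacuole volume fraction %.2f, vacuolar pH %.1f",
                        f_top, p))
    }
    cands
  }

  solution <- NULL
  for (cand in candidate_models()) {
    nh3_cyt <- free_nh3_from_wholecell(obs$nhx_ic, cand$model)
    if (nh3_ec > nh3_cyt) {
      solution <- list(model = cand$model, label = cand$label,
                       nh3_cyt = nh3_cyt)
      break
    }
  }

  strain <- if (is.null(obs$strain)) NA_character_ else as.character(obs$strain)
  if (is.null(solution)) {
    last <- candidate_models()
    worst <- free_nh3_from_wholecell(obs$nhx_ic,
                                     last[[length(last)]]$model)
    return(structure(list(
      strain = strain, ph_ec = obs$ph_ec,
      nh3_cyt_umol = worst * 1e3, nh3_ec_umol = nh3_ec * 1e3,
      cyt_ec_ratio = worst / nh3_ec,
      permeability = NA_real_, adjusted = TRUE,
      adjustment = sprintf(
        paste("infeasible: cytosolic NH3 (%.3g umol/L) >= extracellular",
              "(%.3g umol/L) everywhere in the sensitivity box"),
        worst * 1e3, nh3_ec * 1e3),
      feasible = FALSE, model = last[[length(last)]]$model),
      class = "steady_state_solution"))
  }

  permeability <- estimate_permeability(obs$q_n, nh3_ec, solution$nh3_cyt,
                                        params)
  structure(list(
    strain = strain, ph_ec = obs$ph_ec,
    nh3_cyt_umol = solution$nh3_cyt * 1e3,
    nh3_ec_umol = nh3_ec * 1e3,
    cyt_ec_ratio = solution$nh3_cyt / nh3_ec,
    permeability = permeability,
    adjusted = !is.na(solution$label),
    adjustment = solution$label,
    feasible = TRUE,
    model = solution$model), class = "steady_state_solution")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat(sprintf("<steady_state_solution> %s, pH_EC %.1f\n",
              ifelse(is.na(x$strain), "(unnamed)", x$strain), x$ph_ec))
  cat(sprintf("  NH3 cytosol %.3g umol/L, NH3 extracellular %.3g umol/L\n",
              x$nh3_cyt_umol, x$nh3_ec_umol))
  if (x$feasible) {
    cat(sprintf("  apparent permeability %.3g m/h%s\n", x$permeability,
                if (x$adjusted) paste0(" [adjusted: ", x$adjustment, "]")
                else ""))
  } else {
    cat(sprintf("  infeasible: %s\n", x$adjustment))
  }
  invisible(x)
}

#' @export
as.data.frame.steady_state_solution <- function(x, ...) {
  data.frame(strain = x$strain, pH_EC = x$ph_ec,
             nh3_cyt_umolL = x$nh3_cyt_umol, nh3_ec_umolL = x$nh3_ec_umol,
             cyt_ec_ratio = x$cyt_ec_ratio,
             permeability_m_per_h = x$permeability,
             adjusted = x$adjusted, feasible = x$feasible,
             stringsAsFactors = FALSE)
}

#' Diffusion-limited growth rate at a given extracellular NH3 level
#'
#' Under nitrogen limitation with passive NH3 uptake and a negligible
#' cytosolic NH3 concentration, the growth rate is set by the diffusion
#' flux divided by the biomass nitrogen content:
#' `mu = P * a_m * [NH3]_EC / chi_N`, optionally capped at `mu_max` when
#' another resource becomes limiting.
#'
#' @param nh3_ec Extracellular free NH3, mmol/L (vectorised,
#'   non-negative).
#' @param permeability Apparent permeability P, m/h.
#' @param params [transport_params()]; `mu_max`, when set, caps the rate.
#' @return Specific growth rate, 1/h.
#' @examples
#' growth_rate_from_nh3(0.01, 0.0115)  # linear region
#' @export
growth_rate_from_nh3 <- function(nh3_ec, permeability,
                                 params = transport_params()) {
  check_nonnegative(nh3_ec, "extracellular NH3")
  check_nonnegative(permeability, "permeability")
  mu <- permeability * params$membrane_area * nh3_ec / params$n_content
  if (!is.null(params$mu_max)) mu <- pmin(mu, params$mu_max)
  mu
}

#' Fit the apparent permeability to growth-rate dose-response points
#'
#' Ordinary least squares through the origin of growth rate on
#' extracellular NH3 concentration, restricted to the linear
#' (non-saturated) region; the permeability follows from the slope as
#' `P = slope * chi_N / a_m`.
#'
#' The default linear-region rule keeps points whose NH3 concentration lies
#' below the level at which the fitted line itself predicts half of
#' `mu_max`, iterated to a fixed point (no rule is applied when `mu_max` is
#' not set). An explicit region can be supplied instead, either as a
#' logical/integer index vector or as a scalar upper bound on `nh3_ec`.
#'
#' @param nh3_ec Extracellular free NH3 of each point, mmol/L.
#' @param mu Measured specific growth rate of each point, 1/h.
#' @param params [transport_params()]; `mu_max` drives the default region
#'   rule.
#' @param linear_region `NULL` (default rule), a scalar upper bound on
#'   `nh3_ec`, or an index vector selecting the points to fit.
#' @return List with `permeability` (m/h), `slope` (1/h per mmol/L),
#'   `r_squared` (of the through-origin fit on the selected points),
#'   `n_used` and `region` (the integer indices fitted).
#' @examples
#' c0 <- seq(1e-3, 1e-2, length.out = 10)
#' fit <- fit_permeability_from_growth(c0, 6.6125 * c0)
#' fit$permeability  # 0.0115
#' @export
fit_permeability_from_growth <- function(nh3_ec, mu,
                                         params = transport_params(),
                                         linear_region = NULL) {
  stopifnot(length(nh3_ec) == length(mu), inherits(params, "transport_params"))
  idx <- seq_along(nh3_ec)
  if (is.null(linear_region)) {
    if (!is.null(params$mu_max)) {
      # iterate: fit, cut at the concentration where the line reaches
      # 0.5 * mu_max, refit; converges in a handful of rounds
      keep <- idx
      for (i in 1:20) {
        if (length(keep) < 2L) break
        s <- sum(nh3_ec[keep] * mu[keep]) / sum(nh3_ec[keep]^2)
        cut <- 0.5 * params$mu_max / s
        keep_new <- idx[nh3_ec < cut]
        if (identical(keep_new, keep)) break
        keep <- keep_new
      }
      idx <- keep
    }
  } else if (is.logical(linear_region)) {
    idx <- which(linear_region)
  } else if (length(linear_region) == 1L) {
    idx <- which(nh3_ec < linear_region)
  } else {
    idx <- as.integer(linear_region)
  }
  if (length(idx) < 2L) {
    abort("fewer than 2 points in the selected linear region",
          class = "ammoflux_estimation_error")
  }
  fit <- stats::lm(mu[idx] ~ 0 + nh3_ec[idx])
  slope <- unname(stats::coef(fit)[1])
  # through-origin R^2 (TSS about zero), computed directly
  r2 <- 1 - sum(stats::resid(fit)^2) / sum(mu[idx]^2)
  list(permeability = slope * params$n_content / params$membrane_area,
       slope = slope,
       r_squared = r2,
       n_used = length(idx),
       region = idx)
}
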