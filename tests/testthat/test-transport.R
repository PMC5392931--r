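test_that("diffusion flux is the permeability-area-gradient product", {
  # P = 0.37 m/h over the published pH-6 gradient gives ~0.19 mmol/g/h,
  # consistent with the measured uptake rate 0.183
  q <- diffusion_flux(0.37, 1.47e-3, 1.31e-3)
  expect_equal(q, 0.1906, tolerance = 1e-3)
  expect_identical(diffusion_flux(0.37, 1e-3, 1e-3), 0)
  expect_equal(diffusion_flux(0.74, 1.47e-3, 1.31e-3), 2 * q)
  # sign follows the gradient
  expect_lt(diffusion_flux(0.37, 1e-3, 2e-3), 0)
  expect_error(diffusion_flux(-1, 1e-3, 0), class = "ammoflux_domain_error")
})

test_that("permeability estimation inverts the flux law", {
  # published pH-6 and pH-7 steady states (unrounded concentrations)
  expect_equal(estimate_permeability(0.183, 1.466886e-3, 1.318363e-3),
               0.38265, tolerance = 1e-4)
  expect_equal(estimate_permeability(0.187, 3.187421e-3, 0.904711e-3),
               0.025441, tolerance = 1e-4)
  # round trip with diffusion_flux on random positive gradients
  set.seed(11)
  for (i in 1:20) {
    P <- runif(1, 0.01, 3)
    ec <- runif(1, 1e-4, 5e-3)
    cyt <- runif(1, 0, ec * 0.9)
    q <- diffusion_flux(P, ec, cyt)
    expect_equal(estimate_permeability(q, ec, cyt), P, tolerance = 1e-12)
  }
  expect_error(estimate_permeability(0.2, 1e-3, 2e-3),
               class = "ammoflux_infeasible_error")
  expect_error(estimate_permeability(0, 2e-3, 1e-3),
               class = "ammoflux_domain_error")
})

test_that("steady-state solver reproduces the published deconvolution", {
  obs <- imz351_obs()

  s6 <- solve_steady_state(obs[obs$ph_ec == 6, ])
  expect_false(s6$adjusted)
  expect_true(s6$feasible)
  expect_equal(s6$nh3_cyt_umol, 1.3184, tolerance = 1e-4)
  expect_equal(s6$nh3_ec_umol, 1.4669, tolerance = 1e-4)
  expect_equal(s6$permeability, 0.38265, tolerance = 1e-4)

  s7 <- solve_steady_state(obs[obs$ph_ec == 7, ])
  expect_false(s7$adjusted)
  expect_equal(s7$nh3_cyt_umol, 0.90471, tolerance = 1e-4)
  expect_equal(s7$permeability, 0.025441, tolerance = 1e-4)
})

test_that("the pH-5 steady state takes the vacuolar adjustment path", {
  obs <- imz351_obs()
  s5 <- solve_steady_state(obs[obs$ph_ec == 5, ])
  expect_true(s5$adjusted)
  expect_true(s5$feasible)
  vac <- s5$model$compartments[s5$model$compartments$name == "vacuole", ]
  expect_equal(vac$volume_fraction, 0.25)
  expect_equal(vac$pH, 4.2)
  expect_equal(s5$nh3_cyt_umol, 0.36913, tolerance = 1e-4)
  # full-precision estimate from the printed whole-cell inputs; the small
  # gradient makes this the least certain permeability of the series
  expect_equal(s5$permeability, 2.4659, tolerance = 1e-4)
})

test_that("solver reports infeasibility as a result, not an error", {
  # uniport-strain accumulation cannot be explained by inward diffusion
  s <- solve_steady_state(list(strain = "IME169", ph_ec = 5,
                               nhx_ic = 1.74, nhx_ec = 0.008, q_n = 0.251))
  expect_false(s$feasible)
  expect_true(is.na(s$permeability))
  expect_match(s$adjustment, "infeasible")
  expect_error(solve_steady_state(list(ph_ec = 5, nhx_ic = 1)),
               class = "ammoflux_config_error")
})

test_that("solver round-trips a noise-free forward model exactly", {
  sim <- simulate_chemostat_dataset(
    synthetic_config(true_permeability = 1.0, noise_cv = 0))
  for (i in seq_len(nrow(sim$observations))) {
    s <- solve_steady_state(sim$observations[i, ])
    expect_false(s$adjusted)
    expect_equal(s$permeability, 1.0, tolerance = 1e-12)
  }
})

test_that("vacuolar acidification and growth drive the estimate toward feasibility", {
  base <- cell_model()
  nhx_ic <- 10.5
  deficit <- function(m) free_nh3_from_wholecell(nhx_ic, m)
  # lowering vacuolar pH never raises the cytosolic estimate
  cyt_by_ph <- vapply(seq(5.5, 4.0, by = -0.1), function(p) {
    deficit(set_compartment(base, "vacuole", pH = p))
  }, 0)
  expect_true(all(diff(cyt_by_ph) <= 0))
  # raising vacuolar volume never raises it either
  cyt_by_vf <- vapply(seq(0.14, 0.25, by = 0.01), function(f) {
    deficit(set_compartment(base, "vacuole", volume_fraction = f))
  }, 0)
  expect_true(all(diff(cyt_by_vf) <= 0))
})

test_that("diffusion-limited growth law is linear with a ceiling", {
  # slope P * a_m / chi_N = 6.6125 L/mmol/h at the batch-fit permeability
  expect_equal(growth_rate_from_nh3(1e-3, 0.0115), 6.6125e-3,
               tolerance = 1e-5)
  expect_identical(growth_rate_from_nh3(0, 0.0115), 0)
  capped <- transport_params(mu_max = 0.21)
  expect_equal(growth_rate_from_nh3(10, 0.0115, capped), 0.21)
  # linear below the ceiling
  expect_equal(growth_rate_from_nh3(2e-3, 0.0115),
               2 * growth_rate_from_nh3(1e-3, 0.0115))
})

test_that("through-origin fit recovers the permeability from noiseless points", {
  c0 <- seq(1e-3, 1e-2, length.out = 10)
  fit <- fit_permeability_from_growth(c0, 6.6125 * c0)
  expect_equal(fit$permeability, 0.0115, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
})

test_that("linear-region rule drops saturated points", {
  params <- transport_params(mu_max = 0.21)
  c0 <- c(seq(1e-3, 1e-2, length.out = 8), 0.2)   # last point saturated
  mu <- growth_rate_from_nh3(c0, 0.0115, params)
  fit <- fit_permeability_from_growth(c0, mu, params)
  expect_false(9L %in% fit$region)
  expect_equal(fit$permeability, 0.0115, tolerance = 1e-6)
  # explicit upper bound selects the same region
  fit2 <- fit_permeability_from_growth(c0, mu, params, linear_region = 0.02)
  expect_equal(fit2$permeability, fit$permeability)
  expect_error(fit_permeability_from_growth(1e-3, 6.6e-3),
               class = "ammoflux_estimation_error")
})

test_that("permeability is recovered within 15% from noisy dose-response points", {
  set.seed(42)
  params <- transport_params(mu_max = 0.21)
  design <- expand.grid(dose = c(0.5, 1, 2, 5, 10, 20, 40, 76),
                        ph = c(5, 6, 7))
  nh3 <- speciate(design$dose, design$ph)$nh3
  mu_true <- growth_rate_from_nh3(nh3, 0.0115, params)
  sdlog <- sqrt(log1p(0.1^2))
  mu_noisy <- mu_true * exp(rnorm(length(mu_true), -sdlog^2 / 2, sdlog))
  fit <- fit_permeability_from_growth(nh3, mu_noisy, params)
  expect_lt(abs(fit$permeability / 0.0115 - 1), 0.15)
})

test_that("permeability recovery error stays below 10% median at 5% noise", {
  set.seed(7)
  errs <- vapply(1:200, function(i) {
    P <- exp(runif(1, log(0.03), log(3)))
    sim <- simulate_chemostat_dataset(
      synthetic_config(true_permeability = P, noise_cv = 0.05,
                       n_replicates = 1, ph_setpoints = 6))
    s <- solve_steady_state(sim$observations[1, ])
    abs(s$permeability / P - 1)
  }, 0)
  expect_lt(median(errs), 0.10)
})
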