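test_that("retention factor aggregates volume-weighted speciation", {
  # frozen hand sums: 394.34 + 7872.92 + 0.572 and the pH-5 variant
  expect_equal(retention_factor(cell_model()), 8267.83, tolerance = 1e-5)
  variant <- cell_model(list(compartment("cytosol", 0.70, 6.5),
                             compartment("vacuole", 0.25, 4.2),
                             compartment("mitochondria", 0.01, 7.5)))
  expect_equal(retention_factor(variant), 28445.6, tolerance = 1e-5)
  # single compartment at pH = pKa: 1 * (1 + 1)
  one <- cell_model(list(compartment("cytosol", 1, 9.25)))
  expect_equal(retention_factor(one), 2.0)
  expect_error(cell_model(list()), class = "ammoflux_domain_error")
})

test_that("retention factor decreases in compartment pH", {
  base <- cell_model()
  phs <- seq(4.0, 5.5, by = 0.25)
  rfs <- vapply(phs, function(p) {
    retention_factor(set_compartment(base, "vacuole", pH = p))
  }, 0)
  expect_true(all(diff(rfs) < 0))
})

test_that("cell model enforces its invariants", {
  expect_error(cell_model(list(compartment("a", 0.7, 6.5),
                               compartment("a", 0.2, 4.5))), "unique")
  expect_error(cell_model(list(compartment("a", 0.7, 6.5),
                               compartment("b", 0.4, 4.5))),
               class = "ammoflux_domain_error")
  expect_error(compartment("x", 0, 7), class = "ammoflux_domain_error")
  expect_error(compartment("x", 0.5, 15), class = "ammoflux_domain_error")
})

test_that("whole-cell deconvolution reproduces published cytosolic NH3", {
  # whole-cell 10.9 / 7.48 mmol/L -> 1.32 / 0.90 umol/L free NH3
  expect_equal(free_nh3_from_wholecell(10.9) * 1e3, 1.3184,
               tolerance = 1e-4)
  expect_equal(free_nh3_from_wholecell(7.48) * 1e3, 0.90471,
               tolerance = 1e-4)
  expect_identical(free_nh3_from_wholecell(0), 0)
  expect_error(free_nh3_from_wholecell(-1), class = "ammoflux_domain_error")
})

test_that("deconvolution and aggregation are exact inverses", {
  m <- cell_model()
  for (x in c(1e-6, 1.318e-3, 0.5, 10.9)) {
    expect_equal(free_nh3_from_wholecell(wholecell_from_free_nh3(x, m), m),
                 x, tolerance = 1e-15)
  }
  expect_equal(wholecell_from_free_nh3(1.318363e-3), 10.9,
               tolerance = 1e-6)
})

test_that("compartment profile traps NH4+ in acidic compartments", {
  prof <- compartment_profile(1e-3, cell_model())  # 1 umol/L free NH3
  vac <- prof[prof$name == "vacuole", ]
  expect_equal(vac$nh4, 56.2341, tolerance = 1e-5)  # 10^(9.25-4.5) umol/L
  cyt <- prof[prof$name == "cytosol", ]
  expect_equal(cyt$nh4 / cyt$nh3, 10^2.75, tolerance = 1e-12)
  expect_true(all(prof$nh3 == prof$nh3[1]))
  # volume-weighted total equals the whole-cell value to machine precision
  expect_equal(sum(prof$volume_fraction * prof$nhx),
               wholecell_from_free_nh3(1e-3), tolerance = 1e-15)
  expect_true(all(compartment_profile(0)$nhx == 0))
})

test_that("diffusion ratio prediction matches the published bounds models", {
  max_model <- cell_model(list(compartment("cytosol", 0.70, 6.0),
                               compartment("vacuole", 0.25, 4.0),
                               compartment("mitochondria", 0.01, 7.5)))
  expect_equal(predicted_ratio_diffusion(5, max_model), 2.5699,
               tolerance = 1e-4)
  expect_equal(predicted_ratio_diffusion(6, max_model), 25.686,
               tolerance = 1e-4)
  # identical speciation inside and out: ratio 1
  flat <- cell_model(list(compartment("cytosol", 1, 5)))
  expect_equal(predicted_ratio_diffusion(5, flat), 1.0)
  # concentration-free: prediction needs no concentration input at all
  expect_error(predicted_ratio_diffusion(15), class = "ammoflux_domain_error")
})

test_that("diffusion ratio rises tenfold per pH unit in the trapped regime", {
  for (ph in seq(3, 6, by = 0.5)) {
    q <- predicted_ratio_diffusion(ph + 1) / predicted_ratio_diffusion(ph)
    expect_gte(q, 9.9)
    expect_lte(q, 10.0)
  }
})

test_that("uniport ratio prediction matches the published corner values", {
  en <- membrane_energetics(pmf = -200)
  max_model <- cell_model(list(compartment("cytosol", 0.70, 6.0),
                               compartment("vacuole", 0.25, 4.0),
                               compartment("mitochondria", 0.01, 7.5)))
  min_model <- cell_model(list(compartment("cytosol", 0.70, 7.0),
                               compartment("vacuole", 0.14, 5.5),
                               compartment("mitochondria", 0.01, 7.5)))
  expect_equal(predicted_ratio_uniport(5, max_model, en), 5430.8,
               tolerance = 1e-4)
  expect_equal(predicted_ratio_uniport(5, min_model, en), 108.51,
               tolerance = 1e-4)
  # no driving force, no trapping: ratio collapses to 1
  flat <- cell_model(list(compartment("cytosol", 1, 5)))
  en0 <- membrane_energetics(pmf = -1e-12)
  expect_equal(predicted_ratio_uniport(5, flat, en0), 1.0, tolerance = 1e-9)
  # configuration error without a cytosol
  no_cyt <- cell_model(list(compartment("vacuole", 0.2, 4.5)))
  expect_error(predicted_ratio_uniport(5, no_cyt, en),
               class = "ammoflux_config_error")
})

test_that("uniport ratio rises tenfold per extracellular pH unit", {
  for (ph in seq(3, 6, by = 0.5)) {
    q <- predicted_ratio_uniport(ph + 1) / predicted_ratio_uniport(ph)
    expect_gte(q, 9.9)
    expect_lte(q, 10.0)
  }
})

test_that("ratio bounds bracket the nominal model and collapse on point boxes", {
  for (mech in c("diffusion", "uniport")) {
    b <- ratio_bounds(mech, 6)
    expect_lte(b$min, b$nominal)
    expect_gte(b$max, b$nominal)
  }
  point <- sensitivity_box(vacuole_fraction = c(0.14, 0.14),
                           cytosol_pH = c(6.5, 6.5),
                           vacuole_pH = c(4.5, 4.5))
  b <- ratio_bounds("diffusion", 6, point)
  expect_equal(b$min, b$max)
  expect_equal(b$min, b$nominal)
  expect_error(ratio_bounds("osmosis", 6))
})

test_that("corner-search bounds equal dense-grid extremes on random boxes", {
  set.seed(101)
  en <- membrane_energetics()
  for (i in 1:50) {
    lohi <- function(lo, hi) sort(runif(2, lo, hi))
    box <- sensitivity_box(vacuole_fraction = lohi(0.05, 0.28),
                           cytosol_pH = lohi(5.5, 7.5),
                           vacuole_pH = lohi(3.5, 6.0))
    mech <- if (i %% 2 == 0) "diffusion" else "uniport"
    ph_ec <- runif(1, 4, 7)
    b <- ratio_bounds(mech, ph_ec, box)
    grid <- expand.grid(
      vf = seq(box$vacuole_fraction[1], box$vacuole_fraction[2],
               length.out = 21),
      pc = seq(box$cytosol_pH[1], box$cytosol_pH[2], length.out = 21),
      pv = seq(box$vacuole_pH[1], box$vacuole_pH[2], length.out = 21))
    # independent closed-form oracle, vectorised over the dense grid
    rf <- 0.70 * (1 + 10^(9.25 - grid$pc)) +
      grid$vf * (1 + 10^(9.25 - grid$pv)) + 0.01 * (1 + 10^(9.25 - 7.5))
    vals <- if (mech == "diffusion") {
      rf / (1 + 10^(9.25 - ph_ec))
    } else {
      10^(-en$pmf / en$Z) * 10^(ph_ec - 9.25) * rf /
        (1 + 10^(ph_ec - 9.25))
    }
    expect_equal(b$min, min(vals), tolerance = 1e-12)
    expect_equal(b$max, max(vals), tolerance = 1e-12)
  }
})

test_that("mechanisms are separable across the physiological pH range", {
  for (ph in c(5, 6, 7)) {
    d <- ratio_bounds("diffusion", ph)
    u <- ratio_bounds("uniport", ph)
    expect_gt(u$min, d$max)
  }
  expect_identical(classify_mechanism(4.2, 6), "diffusion")
  expect_identical(classify_mechanism(219, 5), "uniport")
  expect_identical(classify_mechanism(50, 5), "ambiguous")
})
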