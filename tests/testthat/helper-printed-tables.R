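# Published steady-state tables used as reference values across tests.

# Chemostat rate table: measured columns (magnitudes) and the derived
# columns as printed, for both strains at pH 5/6/7, D = 0.05 1/h.
printed_rates <- data.frame(
  strain = rep(c("IME169", "IMZ351"), each = 3),
  ph_ec  = rep(c(5, 6, 7), 2),
  mu     = c(0.053, 0.052, 0.051, 0.047, 0.047, 0.048),
  q_s    = c(3.862, 3.398, 2.953, 3.485, 3.074, 2.826),
  q_o2   = c(1.643, 1.468, 1.273, 1.390, 1.223, 1.239),
  q_co2  = c(7.028, 6.157, 5.218, 6.620, 5.825, 5.081),
  q_etoh = c(4.601, 4.438, 3.608, 4.735, 4.404, 3.639),
  q_n    = c(0.251, 0.223, 0.208, 0.190, 0.183, 0.187),
  n_content = c(4.70, 4.30, 4.06, 4.00, 3.91, 3.88),
  y_xs_printed        = c(0.077, 0.085, 0.096, 0.081, 0.085, 0.095),
  cn_printed          = c(92.3, 91.4, 104.1, 110.1, 100.8, 90.7),
  q_atp_printed       = c(7.72, 7.23, 6.03, 7.38, 6.73, 5.99),
  qatp_per_qn_printed = c(30.8, 32.4, 28.9, 38.9, 36.7, 32.0),
  stringsAsFactors = FALSE
)

# Whole-cell / extracellular NH_X concentrations (mmol/L) and printed
# IC/EC ratios with their mean deviations.
printed_nhx <- data.frame(
  strain = rep(c("IME169", "IMZ351"), each = 3),
  ph_ec  = rep(c(5, 6, 7), 2),
  nhx_ic = c(1.74, 3.16, 3.33, 10.5, 10.9, 7.48),
  nhx_ec = c(0.008, 0.011, 0.013, 6.99, 2.61, 0.57),
  ratio_printed = c(219, 302, 254, 1.5, 4.2, 13.2),
  ratio_dev     = c(39, 40, 10, 0.1, 0.3, 1.3),
  stringsAsFactors = FALSE
)

# Deconvolution results as printed for the diffusion strain: cytosolic and
# extracellular free NH3 (umol/L) and the apparent permeability (m/h).
printed_deconv <- data.frame(
  ph_ec = c(5, 6, 7),
  ph_vac = c(4.2, 4.5, 4.5),
  nh3_cyt_umol = c(0.37, 1.31, 0.90),
  nh3_ec_umol  = c(0.39, 1.47, 3.16),
  permeability = c(2.73, 0.37, 0.03),
  stringsAsFactors = FALSE
)

fixture_path <- function() {
  system.file("extdata", "chemostat_observations.csv", package = "ammoflux")
}

imz351_obs <- function() {
  obs <- read_observations(fixture_path())
  obs[obs$strain == "IMZ351", ]
}
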