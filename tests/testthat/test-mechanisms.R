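test_that("two-exponential conductance: causality, peak, decay, linearity", {
  expect_equal(exp2_conductance(-5, 0.1, 11, 1), 0)
  tp <- 0.1 * 11 / (11 - 0.1) * log(11 / 0.1)
  expect_equal(tp, 0.4745, tolerance = 1e-3)
  expect_equal(exp2_conductance(tp, 0.1, 11, 0.305), 0.305, tolerance = 1e-12)
  # peak is the maximum
  tt <- seq(0, 100, by = 0.01)
  g <- exp2_conductance(tt, 0.1, 11, 1)
  expect_equal(max(g), 1, tolerance = 1e-4)
  expect_lt(exp2_conductance(500, 0.1, 11, 1), 1e-12)
  expect_error(exp2_conductance(1, 11, 11, 1), "smaller")
  # superposition: two events = sum of the single-event conductances
  g2 <- exp2_conductance(tt, 0.5, 37, 1) + exp2_conductance(tt - 10, 0.5, 37, 1)
  expect_equal(g2, exp2_conductance(tt, 0.5, 37, 1) +
                 ifelse(tt >= 10, exp2_conductance(tt - 10, 0.5, 37, 1), 0))
})

test_that("GABA current split follows the fractional-conductance law", {
  # P = 0: pure chloride
  i0 <- gaba_currents(-50, 1, -60, -14, p = 0)
  expect_equal(i0$i_hco3, 0)
  expect_equal(i0$i_cl, 1e-3 * (-50 + 60))
  # P = 0.18 conductance fractions: Cl 1/1.18, HCO3 0.18/1.18
  i2 <- gaba_currents(-50, 2.5, -60, -14, p = 0.18)
  expect_equal(i2$i_cl, 2.5e-3 / 1.18 * (-50 + 60), tolerance = 1e-12)
  expect_equal(i2$i_hco3, 2.5e-3 * 0.18 / 1.18 * (-50 + 14), tolerance = 1e-12)
  # total current vanishes exactly at the weighted reversal
  ecl <- -60; ehc <- -14; p <- 0.18
  vrev <- (ecl + p * ehc) / (1 + p)
  iz <- gaba_currents(vrev, 3, ecl, ehc, p)
  expect_equal(iz$i_cl + iz$i_hco3, 0, tolerance = 1e-15)
  expect_equal(vrev, e_gaba(ecl, ehc, p))
  # linear in g, affine in V
  ia <- gaba_currents(-40, 2, ecl, ehc, p)
  ib <- gaba_currents(-40, 4, ecl, ehc, p)
  expect_equal(ib$i_cl, 2 * ia$i_cl)
  expect_error(gaba_currents(-40, -1, ecl, ehc), ">= 0")
})

test_that("NMDA magnesium block: limits, value, monotonicity", {
  v <- seq(-90, 40, by = 5)
  expect_equal(nmda_block(v, mg = 0), rep(1, length(v)))
  expect_equal(nmda_block(0, mg = 1), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  b <- nmda_block(v, mg = 1)
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 0 & b <= 1))
  expect_lt(nmda_block(-90), nmda_block(0))
})

test_that("tonic currents scale with density and area", {
  z <- tonic_currents(-60, 0, 1e-5, -80, -14)
  expect_equal(z$i_cl, 0); expect_equal(z$i_hco3, 0)
  a <- tonic_currents(-60, 8.75e-6, 1e-5, -80, -14)
  b <- tonic_currents(-60, 8.75e-6, 2e-5, -80, -14)
  expect_equal(b$i_cl, 2 * a$i_cl)
  # at rest above E_Cl the tonic chloride current is an influx (positive)
  expect_gt(a$i_cl, 0)
})

test_that("synapse constructors validate kinetics", {
  expect_warning(g <- gaba_synapse("dend", 0.5, tau_rise = 40, tau_decay = 2),
                 "swapping")
  expect_lt(g$tau1, g$tau2)
  expect_error(ampa_synapse("dend", 0.5, tau1 = 11, tau2 = 11), "smaller")
  expect_error(nmda_synapse("dend", 0.5, mg = -1), ">= 0")
  expect_error(gaba_synapse("dend", 1.5), "\\[0, 1\\]")
})

test_that("HH gates relax to steady state and currents vanish at zero density", {
  st <- hh_step(-60, c(m = 0.2, h = 0.2, n = 0.2, s = 0.2), dt = 0.5,
                gna = 0, gk = 0, gca = 0)
  expect_equal(st$i_na, 0); expect_equal(st$i_k, 0); expect_equal(st$i_ca, 0)
  g <- c(m = 0.2, h = 0.2, n = 0.2, s = 0.2)
  for (i in 1:200) g <- hh_step(-65, g, dt = 1)$gates
  inf <- chloridyn:::hh_gates_inf(-65)
  expect_equal(unname(g[c("m", "h", "n")]), unname(inf[c("m", "h", "n")]),
               tolerance = 1e-6)
})

test_that("suprathreshold injection elicits a spike with HH channels", {
  m <- build_ball_and_stick(dendrite_length = 100, n_dendrite_nodes = 11)
  mech <- mechanism_set(passive = passive_leak(), hh = hh_mechanism())
  cfg <- sim_config(duration = 60, probes = probe("soma", 0.5),
                    iclamp = list(section = "soma", x = 0.5, amp_nA = 0.5,
                                  start = 10, stop = 50))
  r <- integrate_model(m, mech, event_schedule(), ion_state(m, 5), cfg)
  expect_gt(max(r$v), 0)  # V crosses 0 mV at least once
})

test_that("high-threshold Ca conductance leaves chloride transients unchanged", {
  base <- ampa_enhancement(cl0 = 5, n_nodes = 31, dt = 0.05, onset = 200,
                           post = 300, hh = "all")
  ca <- ampa_enhancement(cl0 = 5, n_nodes = 31, dt = 0.05, onset = 200,
                         post = 300, hh = "all", gca = 1e-4)
  expect_equal(ca$metrics_co$delta, base$metrics_co$delta, tolerance = 5e-3)
})
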