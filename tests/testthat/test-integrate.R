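small_setup <- function(nseg = 5, cl0 = 5, tau_gaba = 10) {
  m <- build_ball_and_stick(dendrite_length = 50, n_dendrite_nodes = nseg)
  mech <- mechanism_set(list(gaba = gaba_synapse("dend", 0.5,
                                                 tau_decay = tau_gaba),
                             ampa = ampa_synapse("dend", 0.9)))
  sch <- event_schedule(c("gaba", "ampa"), c(5, 7))
  cfg <- sim_config(duration = 40, dt = 0.05, probes = probe("dend", 0.5),
                    record_every = 0.5)
  list(m = m, mech = mech, sch = sch, ions = ion_state(m, cl0 = cl0),
       cfg = cfg)
}

test_that("resting state is an exact equilibrium", {
  m <- build_ball_and_stick(n_dendrite_nodes = 21)
  mech <- mechanism_set()
  cfg <- sim_config(duration = 200, probes = rbind(probe("dend", 0.5),
                                                   probe("soma", 0.5)))
  r <- integrate_model(m, mech, event_schedule(), ion_state(m, 5), cfg)
  expect_equal(range(r$v), c(-60, -60), tolerance = 1e-9)
  expect_equal(range(r$cl), c(5, 5), tolerance = 1e-9)
  expect_equal(range(r$hco3), c(14.1, 14.1), tolerance = 1e-9)
})

test_that("compiled tree solve equals the dense R reference on a small tree", {
  s <- small_setup()
  r_cpp <- integrate_model(s$m, s$mech, s$sch, s$ions, s$cfg)
  r_ref <- reference_integrate(s$m, s$mech, s$sch, s$ions, s$cfg)
  expect_equal(max(abs(r_cpp$v[, 1] - r_ref$v[, 1])), 0, tolerance = 1e-8)
  expect_equal(max(abs(r_cpp$cl[, 1] - r_ref$cl[, 1])), 0, tolerance = 1e-9)
  # also on a branched morphology with an NMDA synapse
  mb <- morphology(data.frame(
    name = c("soma", "d1", "d2"), length = c(10, 40, 30), diam = c(10, 1, 0.7),
    nseg = c(1, 6, 5), parent = c(NA, "soma", "d1"), attach = c(0, 1, 0.5),
    role = c("soma", "dend", "dend")))
  mech <- mechanism_set(list(g = gaba_synapse("d2", 0.6, tau_decay = 8),
                             n = nmda_synapse("d1", 0.3, g_max = 2)),
                        tonic = tonic_gaba())
  sch <- event_schedule(c("g", "n"), c(2, 2))
  cfg <- sim_config(duration = 25, dt = 0.05, probes = probe("d2", 0.6),
                    record_every = 0.5)
  ions <- ion_state(mb, cl0 = 20)
  r1 <- integrate_model(mb, mech, sch, ions, cfg)
  r2 <- reference_integrate(mb, mech, sch, ions, cfg)
  expect_equal(max(abs(r1$v[, 1] - r2$v[, 1])), 0, tolerance = 1e-7)
  # roundoff accumulates differently in the Hines vs dense elimination
  # order; agreement to ~1e-9 relative on a 20 mM baseline
  expect_equal(max(abs(r1$cl[, 1] - r2$cl[, 1])), 0, tolerance = 1e-6)
})

test_that("anion pools are conserved without transport and flux", {
  m <- build_ball_and_stick(n_dendrite_nodes = 31)
  ions <- ion_state(m, 5)
  # non-uniform initial profile so diffusion is active
  ions$cl[10:15, ] <- 9
  ions$hco3[20, ] <- 20
  cfg <- sim_config(duration = 50, dt = 0.05, probes = probe("dend", 0.5),
                    record_every = 0.5, transport = FALSE)
  r <- integrate_model(m, mechanism_set(), event_schedule(), ions, cfg)
  # 1000 steps of radial + longitudinal diffusion
  expect_lt(max(abs(r$total_cl / r$total_cl[1] - 1)), 1e-9)
  expect_lt(max(abs(r$total_hco3 / r$total_hco3[1] - 1)), 1e-9)
  # concentrations spread but stay positive
  expect_true(all(r$cl >= 0))
})

test_that("membrane potential is conserved at equilibrium over 1000 steps", {
  s <- small_setup()
  cfg <- sim_config(duration = 50, dt = 0.05, probes = probe("dend", 0.1),
                    record_every = 0.5)
  r <- integrate_model(s$m, mechanism_set(), event_schedule(),
                       ion_state(s$m, 12), cfg)
  expect_lt(max(abs(r$v + 60)) / 60, 1e-9)
})

test_that("GABA transient polarity follows the initial chloride level", {
  lo <- chloridyn:::bas_run(cl0 = 5, onset = 200, post = 300, n_nodes = 51,
                            dt = 0.05)
  hi <- chloridyn:::bas_run(cl0 = 25, onset = 200, post = 300, n_nodes = 51,
                            dt = 0.05)
  # low chloride: hyperpolarizing, chloride influx
  expect_lt(min(lo$v[, "syn"]), -60.1)
  expect_lt(max(lo$v[, "syn"]), -59.99)
  expect_gt(measure_transient(lo, "syn", 200)$delta, 0)
  # high chloride: depolarizing, chloride efflux
  expect_gt(max(hi$v[, "syn"]), -59)
  expect_lt(measure_transient(hi, "syn", 200)$delta, 0)
  # E_Cl decreases when chloride rises (monotone Nernst along the trace)
  cl <- lo$cl[, "syn"]
  ecl <- nernst(-1, cl, 133.5)
  # E_Cl shifts toward less negative values (smaller driving force for
  # influx) as chloride accumulates: strictly monotone Nernst
  rising <- diff(cl) > 1e-9
  expect_true(all(diff(ecl)[rising] > 0))
})

test_that("halving dt changes probe traces by less than 0.1%", {
  run_dt <- function(dt) chloridyn:::bas_run(cl0 = 5, onset = 100, post = 150,
                                             n_nodes = 31, dt = dt,
                                             record_every = 1)
  r1 <- run_dt(0.05)
  r2 <- run_dt(0.025)
  r4 <- run_dt(0.0125)
  dv1 <- max(abs(r1$v[, "syn"] - r2$v[, "syn"])) / diff(range(r2$v[, "syn"]))
  expect_lt(dv1, 1e-3)
  dcl1 <- max(abs(r1$cl[, "syn"] - r2$cl[, "syn"])) /
    diff(range(r2$cl[, "syn"]))
  expect_lt(dcl1, 1e-3)
  # at least first-order self-convergence (error shrinks with dt)
  e1 <- max(abs(r1$v[, "syn"] - r4$v[, "syn"]))
  e2 <- max(abs(r2$v[, "syn"] - r4$v[, "syn"]))
  expect_gt(e1 / e2, 1.8)
})

test_that("chloride returns to rest after a single event without overshoot", {
  m <- build_ball_and_stick(dendrite_length = 100, n_dendrite_nodes = 11)
  mech <- mechanism_set(list(gaba = gaba_synapse("dend", 0.5, g_max = 5,
                                                 tau_decay = 10)),
                        passive = passive_leak(sections = "dend"))
  cfg <- sim_config(duration = 400e3, dt = 2, probes = probe("dend", 0.5),
                    record_every = 1e3)
  r <- integrate_model(m, mech, event_schedule("gaba", 100), ion_state(m, 5),
                       cfg)
  peak <- max(r$cl[, 1])
  expect_gt(peak, 5.05)
  final <- r$cl[length(r$time), 1]
  # back within 1% of rest after ~400 s (transport timescale)
  expect_lt(abs(final - 5), 0.01 * 5)
  # no overshoot below rest beyond solver tolerance
  expect_gt(min(r$cl[, 1]), 5 - 1e-6)
})

test_that("schedule validation catches unknown synapses and bad times", {
  s <- small_setup()
  expect_error(integrate_model(s$m, s$mech, event_schedule("nope", 5),
                               s$ions, s$cfg), "unknown synapse")
  expect_error(integrate_model(s$m, s$mech, event_schedule("gaba", 999),
                               s$ions, s$cfg), "within")
})

test_that("long-format export and CSV round trip", {
  s <- small_setup()
  r <- integrate_model(s$m, s$mech, s$sch, s$ions, s$cfg)
  d <- as.data.frame(r)
  expect_setequal(unique(d$quantity), c("v", "cl", "hco3"))
  expect_equal(nrow(d), 3 * length(r$time))
  f <- tempfile(fileext = ".csv")
  write_sim_csv(r, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(d))
  expect_equal(back$value, d$value, tolerance = 1e-12)
  unlink(f)
})
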