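#' Transient metrics from a simulation result
#'
#' @param result a `sim_result`.
#' @param probe probe index or name.
#' @param onset stimulus onset, ms.
#' @param baseline_window ms.
#' @param trace which chloride trace to use: submembrane (`"cl"`) or
#'   volume-averaged (`"cl_mean"`).
#' @return A [delta_cl()] `transient_metrics` object.
#' @export
measure_transient <- function(result, probe = 1, onset,
                              baseline_window = 100, trace = "cl") {
  delta_cl(result[[trace]][, probe], result$time, onset, baseline_window)
}

# shared ball-and-stick run used by the single-synapse protocols
bas_run <- function(cl0, with_gaba = TRUE, with_glu = FALSE,
                    g_gaba = 0.789, tau_gaba = 37, gaba_pos = 0.5,
                    glu = "ampa", g_glu = 0.305, tau_glu = 11,
                    glu_pos = NULL, latency = 0, onset = 500, post = 600,
                    dendrite_length = 200, n_nodes = 103,
                    tonic = FALSE, hh = NULL, gca = 0,
                    dt = 0.025, record_every = 0.25, cm = 1,
                    leak_sections = "dend") {
  morph <- build_ball_and_stick(dendrite_length = dendrite_length,
                                n_dendrite_nodes = n_nodes)
  if (cm != 1) morph$sections$cm <- cm
  if (is.null(glu_pos)) glu_pos <- gaba_pos
  syns <- list()
  ev_syn <- character(0); ev_t <- numeric(0)
  if (with_gaba) {
    syns$gaba <- gaba_synapse("dend", gaba_pos, g_max = g_gaba,
                              tau_decay = tau_gaba)
    ev_syn <- c(ev_syn, "gaba"); ev_t <- c(ev_t, onset)
  }
  if (with_glu) {
    syns$glu <- if (glu == "nmda")
      nmda_synapse("dend", glu_pos, g_max = g_glu)
    else ampa_synapse("dend", glu_pos, g_max = g_glu, tau2 = tau_glu)
    ev_syn <- c(ev_syn, "glu"); ev_t <- c(ev_t, onset + latency)
  }
  pas <- if (tonic) passive_leak(g_pas = 0.99125e-3, sections = leak_sections)
    else passive_leak(sections = leak_sections)
  mech <- mechanism_set(
    synapses = syns, passive = pas,
    tonic = if (tonic) tonic_gaba() else NULL,
    hh = if (is.null(hh)) NULL else
      hh_mechanism(gca = gca, sections = if (hh == "soma") "soma" else NULL))
  pr <- probe("dend", gaba_pos, "syn")
  if (abs(glu_pos - gaba_pos) > 1e-9 && with_glu)
    pr <- rbind(pr, probe("dend", glu_pos, "glu"))
  pr <- rbind(pr, probe("soma", 0.5, "soma"))
  cfg <- sim_config(duration = onset + post, dt = dt, probes = pr,
                    record_every = record_every)
  integrate_model(morph, mech, event_schedule(ev_syn, ev_t),
                  ion_state(morph, cl0 = cl0), cfg)
}

#' Single-synapse chloride-transient experiment
#'
#' Ball-and-stick protocol: one GABA-A synapse in the middle of the
#' dendrite, optionally co-stimulated with a glutamatergic synapse
#' (AMPA or NMDA) at a configurable position and latency. Returns both the
#' GABA-only and the co-stimulation result together with the transient
#' metrics and the glutamatergic enhancement of the chloride transient.
#'
#' @param cl0 initial/resting chloride, mM.
#' @param g_gaba,tau_gaba GABA peak conductance (nS) and decay (ms).
#' @param glu `"ampa"` or `"nmda"`.
#' @param g_glu,tau_glu glutamatergic peak conductance (nS) and decay (ms;
#'   ignored for NMDA which uses its own slow kinetics).
#' @param gaba_pos,glu_pos normalized dendritic positions (default: both
#'   mid-dendrite).
#' @param latency glutamatergic onset relative to the GABA onset, ms.
#' @param onset GABA onset, ms (default 500; the preceding interval sets
#'   the baseline).
#' @param post recorded time after onset, ms.
#' @param dendrite_length,n_nodes dendrite geometry.
#' @param tonic include the tonic GABA conductance (with the passive
#'   conductance reduced to keep the total resting density at 1 mS/cm2).
#' @param hh `NULL`, `"soma"` or `"all"`: add Hodgkin-Huxley channels.
#' @param gca calcium conductance density (S/cm2) when `hh` is set.
#' @param dt,record_every integration/reporting steps, ms.
#' @param cm specific membrane capacitance, uF/cm2.
#' @param leak_sections sections carrying the passive leak (default
#'   `"dend"`: dendritic leak only, which reproduces the ~188 MOhm somatic
#'   input resistance; `NULL` puts the leak on every section).
#' @return List with `gaba` and `co` (`sim_result`s), `metrics_gaba`,
#'   `metrics_co`, and `delta_g` (mM).
#' @export
ampa_enhancement <- function(cl0 = 5, g_gaba = 0.789, tau_gaba = 37,
                             glu = "ampa", g_glu = 0.305, tau_glu = 11,
                             gaba_pos = 0.5, glu_pos = NULL, latency = 0,
                             onset = 500, post = 600,
                             dendrite_length = 200, n_nodes = 103,
                             tonic = FALSE, hh = NULL, gca = 0,
                             dt = 0.025, record_every = 0.25, cm = 1,
                             leak_sections = "dend") {
  args <- list(cl0 = cl0, g_gaba = g_gaba, tau_gaba = tau_gaba, glu = glu,
               g_glu = g_glu, tau_glu = tau_glu, gaba_pos = gaba_pos,
               glu_pos = glu_pos, latency = latency, onset = onset,
               post = post, dendrite_length = dendrite_length,
               n_nodes = n_nodes, tonic = tonic, hh = hh, gca = gca, dt = dt,
               record_every = record_every, cm = cm,
               leak_sections = leak_sections)
  r_gaba <- do.call(bas_run, c(args, list(with_gaba = TRUE, with_glu = FALSE)))
  r_co <- do.call(bas_run, c(args, list(with_gaba = TRUE, with_glu = TRUE)))
  m_gaba <- measure_transient(r_gaba, "syn", onset)
  m_co <- measure_transient(r_co, "syn", onset)
  list(gaba = r_gaba, co = r_co, metrics_gaba = m_gaba, metrics_co = m_co,
       delta_g = delta_g(m_co, m_gaba))
}

#' Distance dependence of the glutamatergic enhancement
#'
#' Long-dendrite protocol: the GABA synapse stays mid-dendrite while the
#' AMPA synapse is moved along the dendrite; the enhancement `delta_g` is
#' computed per position and fitted with a monoexponential over distance.
#'
#' @param positions normalized AMPA positions (default 21 points from the
#'   somatic end to the mid-dendrite GABA site; the somatic-side sweep
#'   decays as a clean monoexponential, whereas the sealed distal end
#'   reflects charge and flattens the distal-side decay).
#' @param leak_sections leak placement for this protocol (default: all
#'   sections).
#' @param cl0 mM (default 5).
#' @param dendrite_length um (default 1000).
#' @param ... passed to [ampa_enhancement()] (e.g. `dt`, `n_nodes`).
#' @return List with `table` (position, distance um, delta_g mM) and
#'   `fit` (a [fit_exp_decay()] result).
#' @export
distance_scan <- function(positions = seq(0, 0.5, by = 0.025), cl0 = 5,
                          dendrite_length = 1000, leak_sections = NULL, ...) {
  args <- list(cl0 = cl0, dendrite_length = dendrite_length,
               leak_sections = leak_sections, ...)
  r_gaba <- do.call(bas_run, c(args, list(with_gaba = TRUE, with_glu = FALSE)))
  onset <- if (is.null(args$onset)) 500 else args$onset
  m_gaba <- measure_transient(r_gaba, "syn", onset)
  dg <- vapply(positions, function(p) {
    r <- do.call(bas_run, c(args, list(with_gaba = TRUE, with_glu = TRUE,
                                       glu_pos = p)))
    delta_g(measure_transient(r, "syn", onset), m_gaba)
  }, 1)
  tab <- data.frame(position = positions,
                    distance = abs(positions - 0.5) * dendrite_length,
                    delta_g = dg)
  list(table = tab, fit = fit_exp_decay(tab$distance, tab$delta_g))
}

#' Kinetics interplay: decay-time scan of the GABA synapse
#'
#' Scans the GABA decay time constant at fixed AMPA kinetics and returns
#' the glutamatergic enhancement per value (simultaneous stimulation).
#'
#' @param tau_values GABA decay time constants, ms (default 5-50 ms in
#'   1 ms steps).
#' @param tau_ampa ms (default 11).
#' @param cl0 mM (default 5, the chloride-influx condition under which the
#'   additional influx is maximal for a decay time slightly above the AMPA
#'   decay time).
#' @param ... passed to [ampa_enhancement()].
#' @return data.frame with `tau_gaba` and `delta_g` (mM).
#' @export
tau_gaba_scan <- function(tau_values = 5:50, tau_ampa = 11, cl0 = 5, ...) {
  dg <- vapply(tau_values, function(tg)
    ampa_enhancement(cl0 = cl0, tau_gaba = tg, tau_glu = tau_ampa,
                     ...)$delta_g, 1)
  data.frame(tau_gaba = tau_values, delta_g = dg)
}

#' Latency dependence of the glutamatergic enhancement
#'
#' @param latencies ms (AMPA onset minus GABA onset; default -49 to 100).
#' @param cl0 mM (default 25).
#' @param ... passed to [ampa_enhancement()].
#' @return data.frame with `latency` and `delta_g` (mM).
#' @export
latency_profile <- function(latencies = seq(-49, 100, by = 1), cl0 = 25, ...) {
  args <- list(cl0 = cl0, ...)
  r_gaba <- do.call(bas_run, c(args, list(with_gaba = TRUE, with_glu = FALSE)))
  onset <- if (is.null(args$onset)) 500 else args$onset
  m_gaba <- measure_transient(r_gaba, "syn", onset)
  dg <- vapply(latencies, function(l) {
    r <- do.call(bas_run, c(args, list(with_gaba = TRUE, with_glu = TRUE,
                                       latency = l)))
    # baseline relative to the earliest stimulus
    delta_g(measure_transient(r, "syn", min(onset, onset + l)), m_gaba)
  }, 1)
  data.frame(latency = latencies, delta_g = dg)
}

#' Chloride response to AMPA input under a tonic GABA conductance
#'
#' No phasic GABA synapse: the membrane carries the tonic GABA-A
#' background conductance (8.75 uS/cm2, with the passive conductance
#' reduced to 0.99125 mS/cm2) and a single mid-dendrite AMPA synapse is
#' activated. The reported quantity is the peak additional submembrane
#' chloride increase at the synapse site relative to a matched run without
#' the AMPA input (the tonic baseline drift cancels in the difference).
#'
#' @param g_ampa AMPA peak conductances to test, nS.
#' @param tau_ampa ms.
#' @param cl0 mM (default 5; the result is nearly independent of it).
#' @param onset,post,dt,record_every timing parameters, ms.
#' @return data.frame with `g_ampa` (nS) and `delta_cl_uM` (peak
#'   additional chloride increase, micromolar).
#' @export
tonic_ampa_experiment <- function(g_ampa = c(0.305, 3.05, 30.5),
                                  tau_ampa = 11, cl0 = 5, onset = 300,
                                  post = 400, dt = 0.025,
                                  record_every = 0.25) {
  base <- bas_run(cl0 = cl0, with_gaba = FALSE, with_glu = FALSE,
                  tonic = TRUE, onset = onset, post = post, dt = dt,
                  record_every = record_every)
  duM <- vapply(g_ampa, function(g) {
    r <- bas_run(cl0 = cl0, with_gaba = FALSE, with_glu = TRUE, g_glu = g,
                 tau_glu = tau_ampa, tonic = TRUE, onset = onset,
                 post = post, dt = dt, record_every = record_every)
    max(r$cl[, "syn"] - base$cl[, "syn"]) * 1e3  # mM -> uM
  }, 1)
  data.frame(g_ampa = g_ampa, delta_cl_uM = duM)
}

# CA3-like run with distributed synapses; returns the mean dendritic
# chloride trace and its transient metrics
ca3_run <- function(morph, locations, schedule, cl0, delay = 200,
                    tail = 300, dt = 0.05, record_every = 1,
                    tonic = FALSE, probe_soma = TRUE) {
  syns <- list()
  for (i in seq_len(nrow(locations$gaba)))
    syns[[sprintf("gdp_gaba%d", i)]] <-
      gaba_synapse(locations$gaba$section[i], locations$gaba$x[i],
                   g_max = locations$g_gaba %||% 0.789,
                   tau_decay = locations$tau_gaba %||% 37)
  if (!is.null(locations$ampa) && nrow(locations$ampa) > 0) {
    for (i in seq_len(nrow(locations$ampa)))
      syns[[sprintf("gdp_ampa%d", i)]] <- if ((locations$glu %||% "ampa") == "nmda")
        nmda_synapse(locations$ampa$section[i], locations$ampa$x[i],
                     g_max = locations$g_glu %||% 0.305)
      else ampa_synapse(locations$ampa$section[i], locations$ampa$x[i],
                        g_max = locations$g_glu %||% 0.305,
                        tau2 = locations$tau_glu %||% 11)
  }
  sched <- event_schedule(schedule$synapse, schedule$time + delay)
  keep <- sched$synapse %in% names(syns)
  sched <- event_schedule(sched$synapse[keep], sched$time[keep])
  s <- morph$sections
  terminal <- s$name[s$role == "dend" & !(s$name %in% s$parent)]
  pr <- do.call(rbind, lapply(terminal, function(d) probe(d, 0.5)))
  if (probe_soma) pr <- rbind(pr, probe("soma", 0.5, "soma"))
  pas <- if (tonic) passive_leak(g_pas = 0.99125e-3) else passive_leak()
  mech <- mechanism_set(synapses = syns, passive = pas,
                        tonic = if (tonic) tonic_gaba() else NULL)
  dur <- (if (nrow(sched) > 0) max(sched$time) else delay) + tail
  cfg <- sim_config(duration = max(dur, delay + tail), dt = dt, probes = pr,
                    record_every = record_every)
  res <- integrate_model(morph, mech, sched, ion_state(morph, cl0 = cl0), cfg)
  md <- mean_dendritic_cl(res, morph)
  list(result = res, mean_cl = md,
       metrics = delta_cl(md$cl, md$time, onset = delay,
                          baseline_window = min(100, delay)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GDP barrage experiment on the CA3-like surrogate
#'
#' Simulates GDP-like barrages (534 GABA inputs, optionally 107
#' glutamatergic inputs) over several seeds and reports the manifest
#' chloride transient of the mean dendritic trace per seed, with and
#' without glutamatergic co-stimulation.
#'
#' @param cl0 mM.
#' @param g_glu glutamatergic peak conductance, nS.
#' @param glu `"ampa"` or `"nmda"`.
#' @param tau_glu AMPA decay, ms.
#' @param seeds integer vector (default 1:9).
#' @param morph morphology (default [build_ca3_like()]).
#' @param spec a [gdp_spec()] (default: compact timing preset).
#' @param with_glu include the glutamatergic inputs.
#' @param tonic include the tonic GABA conductance.
#' @param dt,record_every ms.
#' @return data.frame with one row per seed: `seed`, `delta` (manifest
#'   chloride change of the mean dendritic trace, mM).
#' @export
gdp_experiment <- function(cl0 = 5, g_glu = 0.305, glu = "ampa", tau_glu = 11,
                           seeds = 1:9, morph = build_ca3_like(),
                           spec = gdp_spec(compact = TRUE), with_glu = TRUE,
                           tonic = FALSE, dt = 0.05, record_every = 1) {
  rows <- lapply(seeds, function(sd) {
    g <- gdp_schedule(spec, morph, seed = sd)
    loc <- list(gaba = g$gaba, ampa = if (with_glu) g$ampa else NULL,
                g_glu = g_glu, glu = glu, tau_glu = tau_glu)
    r <- ca3_run(morph, loc, g$schedule, cl0 = cl0, dt = dt,
                 record_every = record_every, tonic = tonic)
    data.frame(seed = sd, delta = r$metrics$delta)
  })
  do.call(rbind, rows)
}

#' Decorrelated-train experiment on the CA3-like surrogate
#'
#' 100 GABA and 100 AMPA synapses stimulated at 20 Hz; the glutamatergic
#' enhancement of the mean dendritic chloride transient is computed per
#' seed for a given AMPA/GABA temporal-correlation mode.
#'
#' @param cl0 mM.
#' @param mode,refractory see [train_spec()].
#' @param seeds integer vector.
#' @param morph morphology (default [build_ca3_like()]).
#' @param duration train duration, ms.
#' @param dt,record_every ms.
#' @return data.frame with one row per seed: `seed`, `delta_gaba`,
#'   `delta_co` and `delta_g` (mM).
#' @export
train_experiment <- function(cl0 = 5, mode = "random", refractory = 0,
                             seeds = 1:9, morph = build_ca3_like(),
                             duration = 1000, dt = 0.05, record_every = 1) {
  spec <- train_spec(mode = mode, refractory = refractory,
                     duration = duration)
  rows <- lapply(seeds, function(sd) {
    set.seed(sd)
    gloc <- place_synapses(morph, spec$n_gaba)
    aloc <- place_synapses(morph, spec$n_ampa)
    sched <- train_schedule(spec, seed = sd)
    sched <- event_schedule(sub("^tr_", "gdp_", sched$synapse), sched$time)
    loc_g <- list(gaba = gloc)
    loc_co <- list(gaba = gloc, ampa = aloc)
    rg <- ca3_run(morph, loc_g, sched, cl0 = cl0, dt = dt,
                  record_every = record_every)
    rc <- ca3_run(morph, loc_co, sched, cl0 = cl0, dt = dt,
                  record_every = record_every)
    data.frame(seed = sd, delta_gaba = rg$metrics$delta,
               delta_co = rc$metrics$delta,
               delta_g = rc$metrics$delta - rg$metrics$delta)
  })
  do.call(rbind, rows)
}
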