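#' Probe specification
#'
#' @param section section name.
#' @param x normalized position in [0, 1]; the probe maps to the nearest
#'   node center.
#' @param name optional probe label (default `"section@x"`).
#' @return A one-row data.frame usable in [sim_config()] (rows can be
#'   concatenated with `rbind`).
#' @export
probe <- function(section, x, name = NULL) {
  data.frame(section = section, x = x,
             name = if (is.null(name)) sprintf("%s@%g", section, x) else name,
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param duration total simulated time, ms.
#' @param dt time step, ms (default 0.025).
#' @param probes data.frame of [probe()] rows.
#' @param record_every reporting interval, ms (default 0.25; snapped to a
#'   multiple of `dt`).
#' @param temperature degrees Celsius (used for the Nernst potentials).
#' @param theta implicitness of the cable step (0.5 = Crank-Nicolson).
#' @param v_init initial membrane potential, mV (default: the leak
#'   reversal).
#' @param iclamp optional current injection,
#'   `list(section=, x=, amp_nA=, start=, stop=)`.
#' @param diffusion,transport logical switches for the ion-diffusion and
#'   relaxation-transport updates (used by conservation tests).
#' @param seed integer seed recorded with the result (generators are seeded
#'   explicitly; the integrator itself is deterministic).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration, dt = 0.025, probes, record_every = 0.25,
                       temperature = .const$temp, theta = 0.5, v_init = NULL,
                       iclamp = NULL, diffusion = TRUE, transport = TRUE,
                       seed = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (duration < dt) stop("duration must be at least dt")
  stopifnot(is.data.frame(probes), all(c("section", "x") %in% names(probes)))
  structure(list(duration = duration, dt = dt, probes = probes,
                 record_every = record_every, temperature = temperature,
                 theta = theta, v_init = v_init, iclamp = iclamp,
                 diffusion = diffusion, transport = transport, seed = seed),
            class = "sim_config")
}

exp2_norm <- function(tau1, tau2) {
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  1 / (exp(-tp / tau2) - exp(-tp / tau1))
}

#' Run a coupled voltage/ion simulation
#'
#' Advances the membrane potential (implicit Crank-Nicolson cable step with
#' conductances and reversal potentials frozen at the step start), the
#' synaptic conductances (analytic two-state update), and the anion state
#' (flux injection at the mid-step voltage, implicit radial and
#' longitudinal diffusion, exponential relaxation transport) on a shared
#' time grid. Chloride and bicarbonate reversal potentials are recomputed
#' from the submembrane shell every step.
#'
#' @param morph a [morphology()].
#' @param mechanisms a [mechanism_set()].
#' @param schedule an [event_schedule()] (may be empty).
#' @param ions an [ion_state()] built from the same morphology.
#' @param config a [sim_config()].
#' @return An object of class `sim_result` with fields `time` (ms), and
#'   per-probe matrices `v` (mV), `cl`, `hco3` (submembrane mM), `cl_mean`
#'   (volume-averaged over shells), `icl` (total chloride current at the
#'   probe node, nA), conservation traces `total_cl`/`total_hco3`
#'   (mM um3), the final state, and the event log.
#' @export
integrate_model <- function(morph, mechanisms, schedule = event_schedule(),
                            ions = ion_state(morph), config) {
  stopifnot(inherits(morph, "morphology"), inherits(mechanisms, "mechanism_set"),
            inherits(ions, "ion_state"), inherits(config, "sim_config"))
  nodes <- ions$nodes
  n <- nrow(nodes)
  pas <- mechanisms$passive

  syns <- mechanisms$synapses
  ids <- names(syns)
  kind_code <- c(gaba = 0L, ampa = 1L, nmda = 2L)
  syn_list <- list(
    node = vapply(syns, function(s) probe_node(nodes, s$section, s$x), 1L) - 1L,
    kind = vapply(syns, function(s) kind_code[[s$kind]], 1L),
    gmax_nS = vapply(syns, `[[`, 1, "g_max"),
    tau1 = vapply(syns, `[[`, 1, "tau1"),
    tau2 = vapply(syns, `[[`, 1, "tau2"),
    nf = vapply(syns, function(s) exp2_norm(s$tau1, s$tau2), 1),
    e_rev = vapply(syns, function(s) if (is.na(s$e_rev)) 0 else s$e_rev, 1),
    p = vapply(syns, function(s) if (is.na(s$p)) 0 else s$p, 1),
    mg = vapply(syns, function(s) if (is.na(s$mg)) 0 else s$mg, 1),
    mg_slope = vapply(syns, function(s) if (is.na(s$mg_slope)) 0.062 else s$mg_slope, 1),
    mg_scale = vapply(syns, function(s) if (is.na(s$mg_scale)) 3.57 else s$mg_scale, 1)
  )
  if (length(syns) == 0)
    syn_list <- lapply(syn_list, function(x) x[0])

  stopifnot(inherits(schedule, "event_schedule"))
  if (nrow(schedule) > 0) {
    bad <- setdiff(unique(schedule$synapse), ids)
    if (length(bad) > 0)
      stop("schedule references unknown synapse id(s): ",
           paste(bad, collapse = ", "))
    if (any(schedule$time < 0 | schedule$time > config$duration))
      stop("event times must lie within [0, duration]")
  }
  ord <- order(schedule$time)
  events <- list(syn = match(schedule$synapse[ord], ids) - 1L,
                 time = schedule$time[ord])
  if (nrow(schedule) == 0) events <- list(syn = integer(0), time = numeric(0))

  # per-node tonic and HH conductances (uS)
  sec_ok <- function(targets) {
    if (is.null(targets)) rep(TRUE, n) else nodes$section %in% targets
  }
  tgcl <- tghco3 <- numeric(n)
  if (!is.null(mechanisms$tonic)) {
    tn <- mechanisms$tonic
    on <- sec_ok(tn$sections)
    g <- tn$density * nodes$area_cm2 * 1e6 * on
    tgcl <- g / (1 + tn$p)
    tghco3 <- g * tn$p / (1 + tn$p)
  }
  gna <- gk <- gca <- numeric(n)
  e_na <- 50; e_k <- -77; e_ca <- 120
  if (!is.null(mechanisms$hh)) {
    hh <- mechanisms$hh
    on <- sec_ok(hh$sections)
    gna <- hh$gna * nodes$area_cm2 * 1e6 * on
    gk <- hh$gk * nodes$area_cm2 * 1e6 * on
    gca <- hh$gca * nodes$area_cm2 * 1e6 * on
    e_na <- hh$e_na; e_k <- hh$e_k; e_ca <- hh$e_ca
  }

  geom <- ions$geom
  node_list <- list(
    parent = ifelse(is.na(nodes$parent), -1L, nodes$parent - 1L),
    gax = ifelse(is.na(nodes$gax_uS), 0, nodes$gax_uS),
    cm_nF = nodes$cm_nF,
    gl_uS = pas$g_pas * nodes$area_cm2 * 1e6 *
      (if (is.null(pas$sections)) 1 else as.numeric(nodes$section %in% pas$sections)),
    e_pas = pas$e_pas,
    area_cm2 = nodes$area_cm2,
    ddx_um = ifelse(is.na(nodes$ddx_um), 1, nodes$ddx_um),
    vol = geom$vol, iface = geom$iface, dr = geom$dr, cross = geom$cross,
    tonic_gcl_uS = tgcl, tonic_ghco3_uS = tghco3,
    gna_uS = gna, gk_uS = gk, gca_uS = gca,
    e_na = e_na, e_k = e_k, e_ca = e_ca
  )

  tr <- ions$transport
  ion_list <- list(
    cl = ions$cl, hco3 = ions$hco3,
    cl_out = ions$cl_out, hco3_out = ions$hco3_out,
    rtf_mV = .const$gas * (config$temperature + .const$celsius0) /
      .const$faraday * 1e3,
    d_cl = ions$diffusion$d_cl, d_hco3 = ions$diffusion$d_hco3,
    cl_rest = tr$cl_rest, hco3_rest = tr$hco3_rest,
    tau_influx_ms = tr$tau_influx * 1e3,
    tau_efflux_ms = tr$tau_efflux * 1e3,
    tau_hco3_ms = tr$tau_hco3 * 1e3
  )

  stride <- max(1L, as.integer(round(config$record_every / config$dt)))
  n_steps <- as.integer(ceiling(config$duration / config$dt))
  if (n_steps %% stride != 0L) n_steps <- n_steps + (stride - n_steps %% stride)

  probes <- config$probes
  pidx <- mapply(function(s, x) probe_node(nodes, s, x), probes$section, probes$x)
  v_init <- if (is.null(config$v_init)) rep(pas$e_pas, n) else
    rep_len(config$v_init, n)
  ic <- config$iclamp
  cfg_list <- list(
    dt = config$dt, n_steps = n_steps, stride = stride, theta = config$theta,
    probes = as.integer(pidx) - 1L, v_init = v_init,
    iclamp_node = if (is.null(ic)) -1L else
      probe_node(nodes, ic$section, ic$x) - 1L,
    iclamp_amp = if (is.null(ic)) 0 else ic$amp_nA,
    iclamp_start = if (is.null(ic)) 0 else ic$start,
    iclamp_stop = if (is.null(ic)) 0 else ic$stop,
    diffusion_on = isTRUE(config$diffusion),
    transport_on = isTRUE(config$transport)
  )

  out <- .engine_run(node_list, syn_list, events, ion_list, cfg_list)
  pn <- if (!is.null(probes$name)) probes$name else
    sprintf("%s@%g", probes$section, probes$x)
  for (f in c("v", "cl", "hco3", "cl_mean", "icl")) colnames(out[[f]]) <- pn
  structure(list(
    time = as.numeric(out$time), v = out$v, cl = out$cl, hco3 = out$hco3,
    cl_mean = out$cl_mean, icl = out$icl,
    total_cl = as.numeric(out$total_cl), total_hco3 = as.numeric(out$total_hco3),
    final = list(cl = out$cl_final, hco3 = out$hco3_final, v = out$v_final),
    events = schedule, probes = probes, config = config
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("<sim_result> %.1f ms in %d records, %d probe(s), ",
                     "%d event(s)\n"),
              max(x$time), length(x$time), ncol(x$v), nrow(x$events)))
  cat(sprintf("  V range [%.2f, %.2f] mV; submembrane [Cl-]_i range [%.3f, %.3f] mM\n",
              min(x$v), max(x$v), min(x$cl), max(x$cl)))
  invisible(x)
}

#' Long-format view of a simulation result
#'
#' @param x a `sim_result`.
#' @param row.names,optional unused (S3 signature).
#' @param quantities which traces to include.
#' @param ... unused.
#' @return data.frame with columns `time`, `probe`, `quantity`, `value`.
#' @export
as.data.frame.sim_result <- function(x, row.names = NULL, optional = FALSE,
                                     quantities = c("v", "cl", "hco3"), ...) {
  out <- do.call(rbind, lapply(quantities, function(q) {
    m <- x[[q]]
    data.frame(time = rep(x$time, ncol(m)),
               probe = rep(colnames(m), each = nrow(m)),
               quantity = q, value = as.vector(m),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write simulation traces to CSV (long format)
#'
#' @param result a `sim_result`.
#' @param path output file.
#' @param quantities which traces to write.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(result, path, quantities = c("v", "cl", "hco3")) {
  write.csv(as.data.frame(result, quantities = quantities), path,
            row.names = FALSE)
  invisible(path)
}
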