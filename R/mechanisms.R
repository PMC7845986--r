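#' Synaptic conductance of a two-exponential synapse
#'
#' `g(t) = g_max N (exp(-t/tau2) - exp(-t/tau1))` for `t >= 0` and 0 before
#' onset, with `N` chosen so that the peak equals `g_max`. Events on one
#' synapse summate linearly.
#'
#' @param t_since_onset ms (vectorized; may be negative).
#' @param tau1,tau2 rise and decay time constants, ms (`tau1 < tau2`).
#' @param g_max peak conductance, nS.
#' @return Conductance in nS.
#' @export
#' @examples
#' exp2_conductance(0.474, 0.1, 11, 1)  # ~1 (the peak)
exp2_conductance <- function(t_since_onset, tau1, tau2, g_max = 1) {
  if (tau1 >= tau2) stop("tau1 must be smaller than tau2")
  if (tau1 <= 0) stop("time constants must be positive")
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  nf <- 1 / (exp(-tp / tau2) - exp(-tp / tau1))
  g <- g_max * nf * (exp(-t_since_onset / tau2) - exp(-t_since_onset / tau1))
  g[t_since_onset < 0] <- 0
  g
}

#' Split a GABA-A current into chloride and bicarbonate components
#'
#' `I_GABA = I_Cl + I_HCO3 = g/(1+P) (V - E_Cl) + g P/(1+P) (V - E_HCO3)`.
#' Positive (outward) anionic current corresponds to anion influx into the
#' cytosol and raises the intracellular concentration.
#'
#' @param v membrane potential, mV.
#' @param g total GABA-A conductance, nS.
#' @param e_cl,e_hco3 reversal potentials, mV.
#' @param p fractional HCO3-/Cl- conductance (default 0.18).
#' @return List with `i_cl` and `i_hco3` in nA.
#' @export
gaba_currents <- function(v, g, e_cl, e_hco3, p = .const$p_hco3) {
  if (any(g < 0)) stop("conductance must be >= 0")
  gus <- g * 1e-3  # nS -> uS so that g*V is in nA
  list(i_cl = gus / (1 + p) * (v - e_cl),
       i_hco3 = gus * p / (1 + p) * (v - e_hco3))
}

#' Magnesium unblock fraction of the NMDA receptor
#'
#' Standard sigmoidal voltage-dependent block,
#' `1 / (1 + Mg/scale * exp(-slope V))`; monotonically increasing in `V`
#' and equal to 1 for magnesium-free conditions.
#'
#' @param v mV.
#' @param mg extracellular magnesium, mM (default 1).
#' @param slope 1/mV (default 0.062).
#' @param scale mM (default 3.57).
#' @return Unblocked fraction in (0, 1].
#' @export
nmda_block <- function(v, mg = 1, slope = 0.062, scale = 3.57) {
  if (any(mg < 0)) stop("mg must be >= 0")
  1 / (1 + mg / scale * exp(-slope * v))
}

#' Tonic GABA-A currents over a membrane patch
#'
#' Same Cl-/HCO3- split law as [gaba_currents()] with `g = density * area`,
#' active continuously (no events).
#'
#' @param v mV.
#' @param density S/cm2 (default 8.75e-6).
#' @param area cm2.
#' @param e_cl,e_hco3 mV.
#' @param p fractional HCO3-/Cl- conductance.
#' @return List with `i_cl` and `i_hco3` in nA.
#' @export
tonic_currents <- function(v, density, area, e_cl, e_hco3, p = .const$p_hco3) {
  if (any(density < 0) || any(area < 0)) stop("density and area must be >= 0")
  gaba_currents(v, density * area * 1e9, e_cl, e_hco3, p)  # S -> nS
}

# ---- synapse constructors -------------------------------------------------

new_synapse <- function(kind, section, x, g_max, tau1, tau2, e_rev = NA,
                        p = NA, mg = NA, mg_slope = NA, mg_scale = NA) {
  if (g_max < 0) stop("g_max must be >= 0")
  if (x < 0 || x > 1) stop("position x must lie in [0, 1]")
  structure(list(kind = kind, section = section, x = x, g_max = g_max,
                 tau1 = tau1, tau2 = tau2, e_rev = e_rev, p = p, mg = mg,
                 mg_slope = mg_slope, mg_scale = mg_scale),
            class = "synapse")
}

#' @export
print.synapse <- function(x, ...) {
  cat(sprintf("<%s synapse> %s(%.3g), g_max = %g nS, tau = %g/%g ms\n",
              x$kind, x$section, x$x, x$g_max, x$tau1, x$tau2))
  invisible(x)
}

#' GABA-A synapse
#'
#' Two-exponential Cl-/HCO3- conductance with dynamic Nernst reversals.
#' If `tau_rise >= tau_decay` the two are swapped with a warning.
#'
#' @param section,x location (section name, normalized position).
#' @param g_max peak conductance, nS (default 0.789).
#' @param tau_rise,tau_decay ms (defaults 0.5 and 37).
#' @param p fractional HCO3-/Cl- conductance (default 0.18).
#' @return A `synapse`.
#' @export
gaba_synapse <- function(section, x, g_max = 0.789, tau_rise = 0.5,
                         tau_decay = 37, p = .const$p_hco3) {
  if (p < 0) stop("p must be >= 0")
  if (tau_rise >= tau_decay) {
    warning("tau_rise >= tau_decay; swapping the two time constants")
    tmp <- tau_rise; tau_rise <- tau_decay; tau_decay <- tmp
  }
  new_synapse("gaba", section, x, g_max, tau_rise, tau_decay, p = p)
}

#' AMPA synapse
#'
#' Two-exponential cation conductance with a fixed reversal potential.
#'
#' @param section,x location.
#' @param g_max peak conductance, nS (default 0.305).
#' @param tau1,tau2 rise/decay time constants, ms (defaults 0.1 and 11).
#' @param e_rev reversal potential, mV (default 0).
#' @return A `synapse`.
#' @export
ampa_synapse <- function(section, x, g_max = 0.305, tau1 = 0.1, tau2 = 11,
                         e_rev = 0) {
  if (tau1 >= tau2) stop("tau1 must be smaller than tau2")
  new_synapse("ampa", section, x, g_max, tau1, tau2, e_rev = e_rev)
}

#' NMDA synapse with magnesium block
#'
#' Two-exponential conductance (slow onset and decay) multiplied by the
#' voltage-dependent unblock fraction of [nmda_block()].
#'
#' @param section,x location.
#' @param g_max peak conductance (at full unblock), nS.
#' @param tau_onset,tau_decay ms (defaults 8.8 and 500).
#' @param e_rev mV (default 0).
#' @param mg extracellular magnesium, mM (default 1).
#' @param mg_slope,mg_scale block parameters (defaults 0.062 /mV, 3.57 mM).
#' @return A `synapse`.
#' @export
nmda_synapse <- function(section, x, g_max = 0.305, tau_onset = 8.8,
                         tau_decay = 500, e_rev = 0, mg = 1,
                         mg_slope = 0.062, mg_scale = 3.57) {
  if (tau_onset >= tau_decay) stop("tau_onset must be smaller than tau_decay")
  if (mg < 0) stop("mg must be >= 0")
  new_synapse("nmda", section, x, g_max, tau_onset, tau_decay, e_rev = e_rev,
              mg = mg, mg_slope = mg_slope, mg_scale = mg_scale)
}

#' Tonic GABA-A background conductance
#'
#' @param density S/cm2 (default 8.75e-6, i.e. 8.75 uS/cm2).
#' @param p fractional HCO3-/Cl- conductance.
#' @param sections character vector of target section names, or `NULL` for
#'   all sections.
#' @return An object of class `tonic_gaba`.
#' @export
tonic_gaba <- function(density = 8.75e-6, p = .const$p_hco3, sections = NULL) {
  if (density < 0) stop("density must be >= 0")
  structure(list(density = density, p = p, sections = sections),
            class = "tonic_gaba")
}

#' Hodgkin-Huxley spiking mechanism
#'
#' Classic m3h/n4 sodium and potassium currents with an optional
#' high-threshold calcium conductance (excluded from the chloride
#' accounting).
#'
#' @param gna,gk peak conductance densities, S/cm2 (defaults 0.12, 0.036).
#' @param gca optional calcium conductance density, S/cm2 (default 0).
#' @param sections target section names, or `NULL` for all.
#' @param e_na,e_k,e_ca reversal potentials, mV.
#' @return An object of class `hh_mechanism`.
#' @export
hh_mechanism <- function(gna = 0.12, gk = 0.036, gca = 0, sections = NULL,
                         e_na = 50, e_k = -77, e_ca = 120) {
  if (any(c(gna, gk, gca) < 0)) stop("densities must be >= 0")
  structure(list(gna = gna, gk = gk, gca = gca, sections = sections,
                 e_na = e_na, e_k = e_k, e_ca = e_ca),
            class = "hh_mechanism")
}

#' Passive leak
#'
#' @param g_pas specific membrane conductance, S/cm2 (default 1 mS/cm2).
#' @param e_pas leak reversal, mV (default -60).
#' @param sections target section names, or `NULL` for all sections. The
#'   single-synapse protocols restrict the leak to the dendrite, which
#'   makes the somatic input resistance equal the dendritic-cable value of
#'   about 188 MOhm (see the methods vignette).
#' @return An object of class `passive_leak`.
#' @export
passive_leak <- function(g_pas = .const$g_pas, e_pas = .const$e_pas,
                         sections = NULL) {
  if (g_pas < 0) stop("g_pas must be >= 0")
  structure(list(g_pas = g_pas, e_pas = e_pas, sections = sections),
            class = "passive_leak")
}

#' Bundle membrane mechanisms for a simulation
#'
#' @param synapses named list of synapses (names become the stable synapse
#'   ids referenced by event schedules); unnamed entries get ids
#'   `syn1, syn2, ...`.
#' @param passive a [passive_leak()].
#' @param tonic a [tonic_gaba()] or `NULL`.
#' @param hh an [hh_mechanism()] or `NULL`.
#' @return An object of class `mechanism_set`.
#' @export
mechanism_set <- function(synapses = list(), passive = passive_leak(),
                          tonic = NULL, hh = NULL) {
  if (inherits(synapses, "synapse")) synapses <- list(synapses)
  stopifnot(all(vapply(synapses, inherits, logical(1), "synapse")))
  nm <- names(synapses)
  if (is.null(nm)) nm <- rep("", length(synapses))
  auto <- sprintf("syn%d", seq_along(synapses))
  nm[nm == ""] <- auto[nm == ""]
  if (any(duplicated(nm))) stop("duplicate synapse ids")
  names(synapses) <- nm
  if (!is.null(tonic)) stopifnot(inherits(tonic, "tonic_gaba"))
  if (!is.null(hh)) stopifnot(inherits(hh, "hh_mechanism"))
  stopifnot(inherits(passive, "passive_leak"))
  structure(list(synapses = synapses, passive = passive, tonic = tonic,
                 hh = hh), class = "mechanism_set")
}

# ---- Hodgkin-Huxley gate kinetics ----------------------------------------

# rate functions; vtrap handles the removable singularities
.vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))

hh_rates <- function(v) {
  list(
    am = 0.1 * .vtrap(-(v + 40), 10), bm = 4 * exp(-(v + 65) / 18),
    ah = 0.07 * exp(-(v + 65) / 20), bh = 1 / (1 + exp(-(v + 35) / 10)),
    an = 0.01 * .vtrap(-(v + 55), 10), bn = 0.125 * exp(-(v + 65) / 80)
  )
}

hh_gates_inf <- function(v) {
  r <- hh_rates(v)
  c(m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh),
    n = r$an / (r$an + r$bn),
    s = 1 / (1 + exp(-(v + 20) / 9)))  # Ca activation
}

#' One Hodgkin-Huxley gate/current step
#'
#' Exact exponential update of the gate variables at fixed voltage over one
#' time step, followed by current evaluation with the m3h/n4 formalism. The
#' optional calcium current uses a high-threshold activation gate `s`
#' (squared) and is excluded from the chloride accounting.
#'
#' @param v mV.
#' @param gates named vector `c(m, h, n, s)` in `[0, 1]`.
#' @param dt ms.
#' @param gna,gk,gca conductance densities, S/cm2.
#' @param e_na,e_k,e_ca mV.
#' @return List with current densities `i_na`, `i_k`, `i_ca` (mA/cm2,
#'   positive outward) and the updated `gates`.
#' @export
hh_step <- function(v, gates, dt, gna = 0.12, gk = 0.036, gca = 0,
                    e_na = 50, e_k = -77, e_ca = 120) {
  stopifnot(all(gates >= 0 & gates <= 1))
  r <- hh_rates(v)
  up <- function(x, a, b) {
    inf <- a / (a + b); tau <- 1 / (a + b)
    inf + (x - inf) * exp(-dt / tau)
  }
  m <- unname(up(gates[["m"]], r$am, r$bm))
  h <- unname(up(gates[["h"]], r$ah, r$bh))
  n <- unname(up(gates[["n"]], r$an, r$bn))
  sinf <- 1 / (1 + exp(-(v + 20) / 9))
  s <- sinf + (gates[["s"]] - sinf) * exp(-dt / 1)  # tau_s = 1 ms
  list(i_na = gna * m^3 * h * (v - e_na),
       i_k = gk * n^4 * (v - e_k),
       i_ca = gca * s^2 * (v - e_ca),
       gates = c(m = m, h = h, n = n, s = s))
}
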