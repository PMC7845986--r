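#' Nernst equilibrium potential
#'
#' @param valence ion valence (e.g. -1 for Cl- and HCO3-).
#' @param c_in,c_out intracellular/extracellular concentration, mM.
#' @param temperature degrees Celsius (default 31).
#' @return Reversal potential in mV, `(RT/zF) ln(c_out/c_in)`.
#' @export
#' @examples
#' nernst(-1, 13.5, 133.5)   # about -60 mV
nernst <- function(valence, c_in, c_out, temperature = .const$temp) {
  if (any(c_in <= 0) || any(c_out <= 0))
    stop("concentrations must be positive")
  if (valence == 0) stop("valence must be non-zero")
  tk <- temperature + .const$celsius0
  (.const$gas * tk / (valence * .const$faraday)) * log(c_out / c_in) * 1e3
}

#' Combined GABA-A reversal potential
#'
#' Conductance-weighted mean of the chloride and bicarbonate reversal
#' potentials, with `p` the fractional HCO3-/Cl- conductance of the
#' receptor: `(E_Cl + p E_HCO3) / (1 + p)`.
#'
#' @param e_cl,e_hco3 mV.
#' @param p fractional HCO3-/Cl- conductance (default 0.18).
#' @return mV.
#' @export
e_gaba <- function(e_cl, e_hco3, p = .const$p_hco3) {
  (e_cl + p * e_hco3) / (1 + p)
}

#' Transmembrane transport parameters
#'
#' Exponential-relaxation stand-in for NKCC1/KCC2-type transport: chloride
#' relaxes toward `cl_rest` with a direction-dependent time constant
#' (`tau_influx` below rest, emulating NKCC1-like uptake; `tau_efflux` above
#' rest, emulating passive efflux). Bicarbonate relaxes toward `hco3_rest`
#' with a single time constant.
#'
#' @param cl_rest resting (set-point) chloride, mM; by convention equal to
#'   the experiment's initial concentration.
#' @param hco3_rest resting bicarbonate, mM (default 14.1).
#' @param tau_influx,tau_efflux,tau_hco3 time constants in seconds
#'   (defaults 174, 321, 174).
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(cl_rest, hco3_rest = .const$hco3_in,
                             tau_influx = .const$tau_influx / 1e3,
                             tau_efflux = .const$tau_efflux / 1e3,
                             tau_hco3 = .const$tau_hco3 / 1e3) {
  if (any(c(tau_influx, tau_efflux, tau_hco3) <= 0))
    stop("all time constants must be positive")
  structure(list(cl_rest = cl_rest, hco3_rest = hco3_rest,
                 tau_influx = tau_influx, tau_efflux = tau_efflux,
                 tau_hco3 = tau_hco3), class = "transport_params")
}

#' Intracellular diffusion parameters
#'
#' @param d_cl,d_hco3 free diffusion coefficients, um2/ms (defaults 2.0 and
#'   1.18).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(d_cl = .const$d_cl, d_hco3 = .const$d_hco3) {
  if (any(c(d_cl, d_hco3) < 0)) stop("diffusion coefficients must be >= 0")
  structure(list(d_cl = d_cl, d_hco3 = d_hco3), class = "diffusion_params")
}

# Radial shell geometry for every node: each node cylinder (radius r,
# length dx) is split into a core plus 4 concentric shells of equal radial
# thickness r/5. Column 1 is the core, column 5 the outermost (submembrane)
# shell. Returns volumes (um3), interface areas between adjacent shells
# (um2), radial center-to-center distance dr (um) and cross-sectional ring
# areas (um2, used for longitudinal coupling).
shell_geometry <- function(nodes) {
  n <- nrow(nodes)
  r <- nodes$diam / 2
  dr <- r / .n_shells
  rb <- outer(r / .n_shells, 0:.n_shells)          # boundaries, n x 6
  ring <- pi * (rb[, -1, drop = FALSE]^2 - rb[, -(.n_shells + 1), drop = FALSE]^2)
  vol <- ring * nodes$dx                            # n x 5, um3
  iface <- 2 * pi * rb[, 2:.n_shells, drop = FALSE] * nodes$dx  # n x 4, um2
  list(vol = vol, iface = iface, dr = dr, cross = ring)
}

#' Per-node, per-shell intracellular anion state
#'
#' Builds the discretized ion state for a morphology: chloride and
#' bicarbonate concentrations in a cylindrical core plus four concentric
#' shells per node, together with the shell geometry, bath concentrations,
#' transport and diffusion parameters.
#'
#' @param morph a [morphology()].
#' @param cl0 initial (and resting) intracellular chloride, mM.
#' @param hco3_0 initial intracellular bicarbonate, mM (default 14.1).
#' @param transport a [transport_params()]; defaults to set point `cl0`.
#' @param diffusion a [diffusion_params()].
#' @param cl_out,hco3_out bath concentrations, mM.
#' @param temperature degrees Celsius.
#' @return An object of class `ion_state`.
#' @export
ion_state <- function(morph, cl0 = 5, hco3_0 = .const$hco3_in,
                      transport = transport_params(cl_rest = cl0),
                      diffusion = diffusion_params(),
                      cl_out = .const$cl_out, hco3_out = .const$hco3_out,
                      temperature = .const$temp) {
  stopifnot(inherits(morph, "morphology"))
  if (cl0 <= 0 || hco3_0 <= 0) stop("initial concentrations must be positive")
  nodes <- morph_nodes(morph)
  n <- nrow(nodes)
  structure(list(
    nodes = nodes,
    geom = shell_geometry(nodes),
    cl = matrix(cl0, n, .n_shells),
    hco3 = matrix(hco3_0, n, .n_shells),
    cl_out = cl_out, hco3_out = hco3_out,
    transport = transport, diffusion = diffusion,
    temperature = temperature
  ), class = "ion_state")
}

#' @export
print.ion_state <- function(x, ...) {
  cat(sprintf(paste0("<ion_state> %d nodes x %d radial compartments\n",
                     "  [Cl-]_i  %.3g mM (submembrane mean), rest %.3g mM\n",
                     "  [HCO3-]_i %.3g mM, bath Cl %.1f / HCO3 %.1f mM\n"),
              nrow(x$cl), ncol(x$cl), mean(x$cl[, .n_shells]),
              x$transport$cl_rest, mean(x$hco3[, .n_shells]),
              x$cl_out, x$hco3_out))
  invisible(x)
}

#' Concentration increment from a transmembrane ionic current
#'
#' Converts an anionic current into the concentration change of the
#' compartment it enters: `dC = I dt / (F V)`. Sign convention (documented
#' once, used everywhere): a positive, outward-directed anionic current
#' corresponds to anion influx and increases the intracellular
#' concentration.
#'
#' @param i_ion current in nA.
#' @param volume compartment volume in um3 (synaptic flux enters the
#'   outermost shell).
#' @param dt time step, ms.
#' @return Concentration increment in mM.
#' @export
#' @examples
#' apply_flux(1e-3, 1, 1)  # 1 pA for 1 ms into 1 um3: ~1.04e-2 mM
apply_flux <- function(i_ion, volume, dt) {
  if (any(volume <= 0)) stop("volume must be positive")
  i_ion * dt / (.const$faraday * volume) * 1e6
}

# backward-Euler tridiagonal exchange among the 5 radial compartments of
# one node; conserves moles exactly (flux form)
.radial_be <- function(conc, vol, iface, dr, d, dt) {
  g <- d * iface / dr                   # um3/ms, 4 couplings
  A <- diag(vol / dt)
  for (k in 1:(.n_shells - 1)) {
    A[k, k] <- A[k, k] + g[k];     A[k, k + 1] <- A[k, k + 1] - g[k]
    A[k + 1, k + 1] <- A[k + 1, k + 1] + g[k]; A[k + 1, k] <- A[k + 1, k] - g[k]
  }
  solve(A, vol * conc / dt)
}

#' One implicit radial-diffusion step
#'
#' Exchanges anions between adjacent radial compartments of every node
#' (flux = `D A_interface dC / dr`), using an unconditionally stable
#' backward-Euler update. Total moles per node are conserved.
#'
#' @param state an [ion_state()].
#' @param dt time step, ms.
#' @return The updated `ion_state`.
#' @export
radial_step <- function(state, dt) {
  g <- state$geom
  for (i in seq_len(nrow(state$cl))) {
    state$cl[i, ] <- .radial_be(state$cl[i, ], g$vol[i, ], g$iface[i, ],
                                g$dr[i], state$diffusion$d_cl, dt)
    state$hco3[i, ] <- .radial_be(state$hco3[i, ], g$vol[i, ], g$iface[i, ],
                                  g$dr[i], state$diffusion$d_hco3, dt)
  }
  state
}

# backward-Euler exchange along the tree for one shell layer of one ion
.longitudinal_be <- function(conc, vol, parent, gax, dt) {
  n <- length(conc)
  A <- diag(vol / dt)
  for (k in seq_len(n)) {
    p <- parent[k]
    if (is.na(p)) next
    A[k, k] <- A[k, k] + gax[k]; A[k, p] <- A[k, p] - gax[k]
    A[p, p] <- A[p, p] + gax[k]; A[p, k] <- A[p, k] - gax[k]
  }
  solve(A, vol * conc / dt)
}

#' One implicit longitudinal-diffusion step
#'
#' Exchanges anions between adjacent node centers along the tree, per shell
#' layer, with the coupling weighted by the shared cross-sectional area of
#' the layer (the smaller of the two ring areas across a diameter change or
#' branch point). Backward Euler; conserves total moles.
#'
#' @param state an [ion_state()].
#' @param dt time step, ms.
#' @return The updated `ion_state`.
#' @export
longitudinal_step <- function(state, dt) {
  nd <- state$nodes
  g <- state$geom
  for (k in seq_len(.n_shells)) {
    cross <- g$cross[, k]
    shared <- ifelse(is.na(nd$parent), NA,
                     pmin(cross, cross[ifelse(is.na(nd$parent), 1, nd$parent)]))
    gcl <- state$diffusion$d_cl * shared / nd$ddx_um
    ghc <- state$diffusion$d_hco3 * shared / nd$ddx_um
    state$cl[, k] <- .longitudinal_be(state$cl[, k], g$vol[, k], nd$parent, gcl, dt)
    state$hco3[, k] <- .longitudinal_be(state$hco3[, k], g$vol[, k], nd$parent, ghc, dt)
  }
  state
}

#' One exponential-relaxation transport step
#'
#' Relaxes concentrations toward their resting set points with the exact
#' exponential update (unconditionally stable). For chloride the time
#' constant is chosen per node from the sign of the submembrane deviation:
#' `tau_influx` (NKCC1-like, default 174 s) below rest and `tau_efflux`
#' (passive, default 321 s) above rest; bicarbonate uses a single time
#' constant. The same factor is applied to every shell of the node.
#'
#' @param state an [ion_state()].
#' @param dt time step, ms.
#' @return The updated `ion_state`.
#' @export
relaxation_step <- function(state, dt) {
  tr <- state$transport
  below <- state$cl[, .n_shells] < tr$cl_rest
  tau_cl <- ifelse(below, tr$tau_influx, tr$tau_efflux) * 1e3  # s -> ms
  fac <- exp(-dt / tau_cl)
  state$cl <- tr$cl_rest + (state$cl - tr$cl_rest) * fac
  fhc <- exp(-dt / (tr$tau_hco3 * 1e3))
  state$hco3 <- tr$hco3_rest + (state$hco3 - tr$hco3_rest) * fhc
  state
}

# total intracellular moles (attomol = mM * um3 * 1e-18 mol; reported in
# mM*um3 units, only ratios matter in the tests)
total_moles <- function(state) {
  c(cl = sum(state$cl * state$geom$vol), hco3 = sum(state$hco3 * state$geom$vol))
}
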