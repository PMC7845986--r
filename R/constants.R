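# Central unit/constant table. Internal units throughout the package:
# mV, ms, nA, mM, um, uS, nF, uF/cm2, S/cm2, Ohm*cm.
# Derived conversions used below:
#   capacitance  [nF] = Cm [uF/cm2] * area [cm2] * 1e3
#   conductance  [uS] = g  [S/cm2]  * area [cm2] * 1e6;  1 nS = 1e-3 uS
#   current      [nA] = g [uS] * V [mV]
#   flux to conc [mM] = I [nA] * dt [ms] / (F * vol [um3]) * 1e6

.const <- list(
  faraday    = 96485,     # C/mol
  gas        = 8.314,     # J/(mol K)
  celsius0   = 273.15,
  # extracellular bath (fixed)
  cl_out     = 133.5,     # mM
  hco3_out   = 24,        # mM
  hco3_in    = 14.1,      # mM, resting intracellular bicarbonate
  # GABA-A anion permeability split
  p_hco3     = 0.18,      # fractional HCO3-/Cl- conductance
  # intracellular diffusion coefficients
  d_cl       = 2.0,       # um2/ms
  d_hco3     = 1.18,      # um2/ms
  # relaxation transport time constants (bimodal chloride rule)
  tau_influx = 174e3,     # ms, NKCC1-like uptake, applies when [Cl-]_i < rest
  tau_efflux = 321e3,     # ms, passive efflux, applies when [Cl-]_i > rest
  tau_hco3   = 174e3,     # ms, bicarbonate relaxation (both directions)
  # passive membrane
  g_pas      = 1e-3,      # S/cm2
  e_pas      = -60,       # mV
  ra         = 34.5,      # Ohm cm
  cm         = 1.0,       # uF/cm2
  temp       = 31         # degrees C
)

#' Physical constants and model defaults
#'
#' Returns the package-wide table of physical constants and default model
#' parameters (Faraday constant, bath concentrations, diffusion coefficients,
#' transport time constants, passive membrane parameters). All unit
#' conversions in the package are derived from this single table.
#'
#' @return Named list of constants.
#' @export
#' @examples
#' chloridyn_constants()$faraday
chloridyn_constants <- function() .const

# number of radial compartments per node: cylindrical core + 4 shells
.n_shells <- 5L
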