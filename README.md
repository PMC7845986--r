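# chloridyn

Biophysical simulation of activity-dependent intracellular chloride
dynamics on neuronal cables, for computational neuroscientists studying
GABAergic ionic plasticity — the process by which chloride flux through
GABA_A receptors changes [Cl-]_i, shifts E_Cl, and thereby alters the
amplitude and polarity of subsequent GABAergic responses, particularly
under coincident glutamatergic depolarization.

## The model

A compartmental cable model (Crank–Nicolson on the tree, Hines solver,
Rcpp core) is coupled to per-node intracellular anion dynamics:

* GABA_A synapses carry parallel Cl-/HCO3- conductances,

  `I_GABA = g/(1+P) (V − E_Cl) + gP/(1+P) (V − E_HCO3)`,  P = 0.18,

  with both reversal potentials recomputed every time step from the local
  submembrane concentrations (Nernst, 31 °C, [Cl-]_o = 133.5 mM,
  [HCO3-]_o = 24 mM).
* Each node's volume is a cylindrical core plus four concentric shells;
  synaptic flux enters the submembrane shell (`d[A-]/dt = I/(F·V)`),
  anions diffuse radially between shells and longitudinally along the
  tree (D_Cl = 2, D_HCO3 = 1.18 µm²/ms; implicit, mole-conserving).
* Transmembrane transport is an exponential relaxation toward the resting
  set point with a bimodal chloride time constant: τ = 174 s below rest
  (NKCC1-like uptake), τ = 321 s above rest (passive efflux).
* AMPA (0.1/11 ms), NMDA (8.8/500 ms with sigmoidal Mg block), tonic
  GABA conductance (8.75 µS/cm²) and Hodgkin–Huxley spiking are available.

Stimulation protocols are generated in-package: single/paired synapse
parameter scans on a ball-and-stick cell, GDP-like barrages (534 GABA +
107 AMPA inputs with normal-distributed onset times) on a CA3-like
surrogate tree, and 20 Hz random trains with refractory decorrelation.
Analysis functions compute the transient amplitude Δ[Cl-]_i (manifest,
min/max), the glutamatergic enhancement Δ_G[Cl-]_i, phase-plane
trajectories, monoexponential length-constant fits and event
cross-correlograms.

## Worked example

A single GABA_A synapse (0.789 nS, τ = 37 ms) in the middle of a
200 µm dendrite, with and without a coincident AMPA input (0.305 nS,
τ = 11 ms), at a low initial chloride level:

```r
library(chloridyn)
r <- ampa_enhancement(cl0 = 5)   # 5 mM resting chloride
r$metrics_gaba
#> <transient_metrics> baseline 5.000 mM, delta_min 0.0000 / delta_max 0.2920, manifest 0.2920 mM
r$metrics_co
#> <transient_metrics> baseline 5.000 mM, delta_min 0.0000 / delta_max 0.3012, manifest 0.3012 mM
r$delta_g
#> [1] 0.009170639
```

At 5 mM the GABAergic driving force is inward: the synapse hyperpolarizes
the membrane and raises chloride at the synapse by 0.29 mM; the AMPA
co-stimulus depolarizes the membrane during the GABA conductance,
increasing the influx by Δ_G ≈ 0.009 mM. Running the same protocol at
`cl0 = 25` flips the response (depolarizing GABA, chloride efflux), and
the co-stimulus then attenuates the efflux — the two faces of
glutamatergic modulation of ionic plasticity.

Higher-level protocols follow the same pattern, e.g.

```r
distance_scan()$fit        # lambda ~ 251 um decay of delta_G with synapse distance
tau_gaba_scan()            # enhancement vs GABA decay time (peak near 16 ms)
tonic_ampa_experiment()    # microM chloride responses under tonic GABA
gdp_experiment(cl0 = 5)    # barrage transients on the CA3-like tree, 9 seeds
```

or from a shell via the bundled CLI and YAML presets:

```sh
Rscript inst/cli/chloridyn run --preset tonic --out results/
Rscript inst/cli/chloridyn scan --param g_ampa --grid 0.305,3.05,30.5
```

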