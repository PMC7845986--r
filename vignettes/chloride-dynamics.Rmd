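---
title: "Modeling activity-dependent chloride dynamics in neuronal cables"
author: "chloridyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling activity-dependent chloride dynamics in neuronal cables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chloridyn)
```

## The problem

GABA~A~ receptors are anion channels with a high Cl^-^ and a lower HCO~3~^-^
permeability. Whether GABA inhibits or excites a neuron therefore hinges on
the transmembrane chloride gradient — and that gradient is itself changed by
GABAergic activity: chloride flux through the receptor shifts
[Cl^-^]~i~, moves E~Cl~, and thereby changes the amplitude and even the
polarity of subsequent GABAergic responses ("ionic plasticity"). A
coincident glutamatergic depolarization changes the driving force
E~m~ − E~GABA~ during the GABAergic conductance and so modulates how much
chloride moves. `chloridyn` simulates this interaction quantitatively on
neuronal cable models and quantifies it with the transient metrics used in
the experimental literature.

## The model

**Electrical compartment model.** A morphology is a rooted tree of
cylindrical sections discretized into nodes (centers at `(i - 0.5)/nseg`).
Each node carries a membrane capacitance (C~m~ = 1 µF/cm²), a passive leak
(g~pas~, reversal −60 mV) and whatever synaptic, tonic or voltage-gated
conductances are placed on it; neighboring nodes are coupled through axial
resistances computed from R~a~ = 34.5 Ω·cm. The soma is modeled as an
isopotential cylinder with length equal to its diameter, so its lateral
area equals the surface of a sphere of the same diameter. The cable
equation is advanced with a Crank–Nicolson step solved by Hines-ordered
elimination on the tree (exact O(n) per step); conductances and reversal
potentials are frozen over each step, with synaptic conductances evaluated
analytically at the step midpoint, which makes the voltage update
effectively second-order in `dt` (the default `dt` of 0.025 ms changes
traces by about 0.01% when halved).

**Synapses.** All phasic conductances are two-state (difference of
exponentials), peak-normalized so that `g_max` is the literal peak
conductance, with events summating linearly. The GABA~A~ conductance is
split into Cl^-^ and HCO~3~^-^ components by the fractional conductance
P = 0.18:

$$I_{GABA} = \tfrac{1}{1+P}\,g(t)\,(V - E_{Cl}) +
            \tfrac{P}{1+P}\,g(t)\,(V - E_{HCO_3}),$$

with both reversal potentials recomputed every step from the local
submembrane concentrations by the Nernst equation at 31 °C
([Cl^-^]~o~ = 133.5 mM, [HCO~3~^-^]~o~ = 24 mM, [HCO~3~^-^]~i~ starting at
14.1 mM). AMPA synapses are ordinary two-exponential conductances
(0.1/11 ms, reversal 0 mV); NMDA synapses use slow kinetics
(8.8/500 ms) multiplied by the standard sigmoidal magnesium unblock
`1/(1 + Mg/3.57 · exp(−0.062 V))` with Mg = 1 mM. A tonic GABA~A~
background conductance (default 8.75 µS/cm²) uses the same anionic split,
continuously. Classic Hodgkin–Huxley Na/K channels (exact-exponential gate
updates) and a high-threshold Ca conductance can be added; the Ca current
is deliberately excluded from the chloride bookkeeping.

**Sign convention** (used everywhere): a positive, outward-directed
anionic current means anion influx and increases the intracellular
concentration, `d[A^-]/dt = I/(F·V)`.

**Intracellular anion dynamics.** Each node's volume is divided into a
cylindrical core plus four concentric shells of equal radial thickness
(r/5). Synaptic and tonic anion fluxes enter the outermost (submembrane)
shell; reported "chloride at the synapse" is the submembrane value (a
volume-averaged trace is also recorded — for the default 1 µm dendrite
radial mixing is fast enough that the two are nearly identical). Radial
exchange between adjacent shells (flux `D·A·ΔC/Δr`) and longitudinal
exchange between node centers (per shell layer, coupling weighted by the
smaller shared ring cross-section, branch points distributing by area) are
integrated with unconditionally stable backward-Euler updates whose
constant matrices are prefactored once; both conserve moles to solver
roundoff. Free diffusion coefficients are 2.0 µm²/ms (Cl^-^) and
1.18 µm²/ms (HCO~3~^-^). Electrodiffusion is deliberately not modeled.

**Transport as relaxation.** Rather than mechanistic NKCC1/KCC2 kinetics,
transmembrane transport is an exponential relaxation of each node toward
its resting set point, `d[A^-]/dt = ([A^-]_rest − [A^-])/τ`, applied with
the exact exponential update. Chloride uses the bimodal rule: τ = 174 s
below rest (NKCC1-like uptake) and τ = 321 s above rest (passive efflux),
selected per node from the submembrane deviation and applied to all its
shells. The set point equals the experiment's initial concentration
[Cl^-^]~i~^0^, which is the quantity scanned (5–40 mM) across experiments.
Bicarbonate relaxes toward 14.1 mM with a single configurable τ
(default 174 s both directions; no direction-dependence is claimed for it).

**Operator splitting.** Per time step: deliver due events → assemble
frozen conductances and reversals → implicit cable solve → update HH gates
at the new voltage → inject anionic fluxes at the mid-step voltage →
radial diffusion → longitudinal diffusion → relaxation transport. A pure-R
reference implementation of the identical loop (dense linear algebra)
lives in the test suite and the compiled tree solver is checked against it
on small morphologies.

## Outcome measures

`delta_cl()` quantifies a transient against the mean of the last 100 ms
before stimulus onset; for biphasic responses both extremes are kept and
the *manifest* amplitude is the larger-magnitude deviation (ties resolve
to the maximum branch). `delta_g()` — the glutamatergic enhancement — is
the difference between the manifest amplitudes with and without
co-stimulation. `phase_plane()` plots the central-difference rate of
change (mM/s) against the deviation; `fit_exp_decay()` fits
`A·exp(−x/λ)` over distance (log-linear seeding, `nls`);
`crosscorrelogram()` histograms AMPA−GABA event-time differences.
Repetition experiments report mean ± SD over seeds (9 by default);
group contrasts, where needed, use Welch's t-test.

## Stimulation protocols (the synthetic-data layer)

The package generates its own input patterns, emulating the statistical
structure of recorded immature-hippocampus activity:

* **Single/paired synapse protocols** — one GABA synapse mid-dendrite of a
  ball-and-stick cell (soma d = 20 µm; dendrite 200 µm × 1 µm, 103 nodes;
  1000 µm for the spatial scan), optionally co-stimulated by one AMPA or
  NMDA synapse at a configurable position and latency (−49…+100 ms).
* **GDP-like barrages** — 534 GABA and 107 AMPA synapses placed uniformly
  over dendritic length, each firing once, onset times drawn from normal
  distributions (GABA µ = 600 ms, AMPA µ = 650 ms) truncated by resampling
  into a 1.3 s window. The nominal sigmas (9000/8500 ms) are so wide that
  truncation makes the distribution near-uniform and no event surge forms;
  the compact preset (`gdp_spec(compact = TRUE)`, σ = 90/85 ms) produces
  the expected GDP-like depolarizing envelope and is what the qualitative
  barrage checks use.
* **20 Hz random trains with decorrelation** — 100 GABA and 100 AMPA
  synapses driven by a Poisson event stream at 20 Hz. The rate is treated
  as a *population* rate (each event activates one randomly chosen
  synapse): a per-synapse reading would put ~2000 events in a 1 s window,
  within which no AMPA time could stay 37 ms away from every GABA time, so
  the published refractory decorrelation (5/11/37 ms, rejection sampling
  with a 10,000-draw cap) would be infeasible; the small published effect
  sizes (~0.04 mM) also imply tens of events. The per-synapse reading
  remains available (`rate_mode = "per_synapse"`).
* **Placement rules** — uniform over dendritic length (default),
  colocalized-with-GABA, and proximal/distal-quarter restrictions. The
  source study drew placements from a normal distribution over dendrite
  index; placement statistics enter these results only through totals, so
  the uniform rule is used as the cleaner default.

## Where the published parameters are internally inconsistent

Two printed statements cannot both hold, and the package resolves them per
protocol, matching each protocol's printed *outcome*:

* With g~pas~ = 1 mS/cm² on soma *and* dendrite the ball-and-stick input
  resistance is ~56 MΩ, yet the source model reports 188.2 MΩ — which is
  exactly the input resistance of the dendritic cable alone
  (R~∞~·coth(l/λ) ≈ 188 MΩ). Confining the leak to the dendrite
  (`leak_sections = "dend"`, the default of the single-synapse protocols)
  reproduces both the 188 MΩ figure and the micromolar tonic-conductance
  AMPA responses (0.10/0.87/3.85 µM at 0.305/3.05/30.5 nS vs the published
  0.1/0.85/3.74 µM; with a uniform leak these come out ~2× too small).
* The spatial-decay experiment, by contrast, reproduces its published
  length constant with the uniform leak the methods state:
  sweeping the AMPA synapse over the somatic half of a 1000 µm dendrite
  yields λ = 251 µm (R² = 0.999) against the published 248 µm. The distal
  half is excluded from the default fit because the sealed distal end
  reflects charge and flattens the decay there (λ ≈ 360 µm) — visible in
  the symmetric two-branch scan, which `distance_scan()` can still
  produce on request.

Both switches are plain arguments, so either convention can be forced for
any protocol.

## The CA3-like surrogate tree

The reconstructed immature CA3 pyramidal cell used for the barrage
experiments is not redistributable here, and its dendrite lengths are not
published. `build_ca3_like()` therefore builds a calibrated stellate
surrogate with the published section inventory — soma d = 15 µm, trunk
2 × 32 µm (9 segments), 56 dendrites of d = 0.36 µm (9 segments each) —
and a free dendrite length, defaulting to 150 µm (a realistic
immature-CA3 value). `calibrate_dendrite_length()` bisects the length
against an input-resistance target; note that with the published passive
parameters the isopotential soma alone caps whole-cell R~in~ near
134 MΩ, so the 188.2 MΩ target is unreachable for any length and the
function then warns and returns the closest bracket end. Results on this
surrogate are treated as qualitative (signs, orderings, waveform shape),
never as quantitative reproduction of the reconstructed-cell numbers.

## Numerical choices and degenerate inputs

* `dt` = 0.025 ms (configurable); implicit voltage and diffusion updates
  mean `dt` is never stability-limited, only accuracy-limited.
* Events are delivered at the first step whose start time reaches the
  event time; probes snap to the nearest node center.
* Zero-length regions for placement, empty scan grids, schedules naming
  unknown synapses, events outside the run window, non-positive
  concentrations in the Nernst equation, and τ₁ ≥ τ₂ kinetics are all
  rejected with informative errors (GABA constructors swap reversed time
  constants with a warning instead, matching common usage).
* A constant profile passed to the exponential fit is flagged
  non-identifiable (λ = ∞) rather than fitted.
* Divergence (non-finite voltage) aborts the compiled loop with the
  simulated time in the message.

## Problem sizes used by the shipped checks

The test suite runs the full-resolution single-synapse protocols
(103-node dendrite, `dt` = 0.025 ms) for the quantitative checks: the
21-position distance scan, the 46-value τ~GABA~ scan, and the
three-point tonic series. Barrage and train checks on the CA3-like
surrogate use `dt` = 0.05 ms, 1 ms reporting, and 3 seeds per condition;
the user-facing defaults remain 9 repetitions (seeds 1–9), reported as
mean ± SD. The oracle-equivalence comparisons run on ≤ 20-node trees
where the dense reference solver is exact and fast.

## What passing tests do and do not show

The synthetic protocols emulate the *statistics* of the recorded inputs
(counts, rates, timing distributions, placement), not their biological
correlations: no network mechanism generates the barrages, transport is a
phenomenological relaxation rather than transporter kinetics with ion
stoichiometry, Na^+^/K^+^ accumulation and pH/carbonic-anhydrase chemistry
are not modeled, and extracellular concentrations are clamped. Agreement
on the desk-scale targets therefore validates the electro-diffusive
chloride bookkeeping and the protocol logic, not the full physiology of a
developing neuron; conclusions about real cells inherit every one of
these simplifications.

## Known limitations

* No electrodiffusion: concentration changes do not feed back on the
  axial voltage equation, and large local gradients (thin dendrites,
  strong stimulation) are where that approximation is weakest.
* The CA3-like surrogate reproduces orderings and signs, not the absolute
  barrage amplitudes of the reconstructed morphology.
* HH kinetics are the classic squid formalism with a −60 mV leak, used
  only for qualitative spike-enhancement demonstrations.
* HDF5 export is not provided; full shell-resolved state is available
  in-memory from the returned result and via CSV/JSON exports.
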