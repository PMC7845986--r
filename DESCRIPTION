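Package: chloridyn
Title: Activity-Dependent Chloride Dynamics in Compartmental Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical simulation of activity-dependent intracellular chloride
    dynamics on neuronal cables. Implements a compartmental cable solver coupled
    to GABA-A receptor currents with separate Cl-/HCO3- components and dynamic
    Nernst reversal potentials, AMPA and NMDA (Mg-blocked) synapses, tonic GABA
    conductances and Hodgkin-Huxley spiking; intracellular ion handling uses
    radial shells, longitudinal diffusion along the dendritic tree and
    exponential-relaxation transmembrane transport with direction-dependent time
    constants (NKCC1-like uptake vs passive efflux). Ships stimulation-protocol
    generators (single-synapse parameter scans, giant-depolarizing-potential-like
    barrages, decorrelated 20 Hz trains) and analysis of the resulting chloride
    transients (transient amplitudes, glutamatergic enhancement, phase planes,
    length-constant fits, cross-correlograms).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
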