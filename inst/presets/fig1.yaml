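# Single GABA synapse mid-dendrite with AMPA co-stimulation at a low
# initial chloride level; writes full E_m/[Cl-]_i traces plus metrics.
# Repeat with params.cl0: 15 and 25 for the other conditions.
experiment: single
seed: 1
params:
  cl0: 5
  g_gaba: 0.789
  tau_gaba: 37
  g_glu: 0.305
  tau_glu: 11
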