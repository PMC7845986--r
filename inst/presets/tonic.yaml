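# AMPA-only responses under the tonic GABA background conductance
experiment: tonic_ampa
seed: 1
params:
  g_ampa: [0.305, 3.05, 30.5]
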