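# GDP-like barrage on the CA3-like surrogate, 9 repetitions
experiment: gdp
seed: 1
params:
  cl0: 5
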