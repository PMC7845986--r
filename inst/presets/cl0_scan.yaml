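# Manifest chloride transients with/without AMPA across initial chloride
experiment: scan
seed: 1
params:
  param: cl0
  grid: [5, 10, 15, 20, 25, 30, 35, 40]
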