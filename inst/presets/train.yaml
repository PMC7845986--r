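# 20 Hz decorrelation train protocol on the CA3-like surrogate
experiment: train
seed: 1
params:
  cl0: 5
  mode: refractory
  refractory: 11
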