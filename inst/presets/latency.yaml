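# AMPA/GABA latency profile of the chloride-transient enhancement
experiment: latency_profile
seed: 1
params:
  latencies: [-40, -20, -10, -5, 0, 5, 10, 15, 20, 25, 30, 40, 60, 100]
  cl0: 25
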