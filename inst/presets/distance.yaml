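# Distance scan on the 1000 um dendrite with monoexponential fit
experiment: distance_scan
seed: 1
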