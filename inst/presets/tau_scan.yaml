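# GABA decay-time scan at fixed AMPA kinetics
experiment: tau_gaba_scan
seed: 1
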