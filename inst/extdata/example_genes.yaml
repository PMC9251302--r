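# Downstream gene specifications: Hill coefficient h, effective affinity
# K (uM), and optionally gamma/delta/Gamma/Delta kinetic overrides.
Protein1: {h: 2, K: 0.05}
Protein2: {h: 4, K: 0.8}
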