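# Peptides of interest on beta-2-glycoprotein I (mature-chain numbering).
# Spans are inclusive on both ends.
loop_33_36: 33-36
epitope_39_43: 39-43
helix_50_56: 50-56
linker_63_67: 63-67
loop_106_109: 106-109
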