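>b2gpi_di_dii mature beta-2-glycoprotein I residues 1-120 (domains I-II, UniProt P02749 numbering of the mature chain)
GRTCPKPDDLPFSTVVPLKTFYEPGEEITYSCKPGYVSRGGMRKFICPLT
GLWPINTLKCTPRVCPFAGILENGAVRYTTFEYPNTISFSCNTGFYLNGA
DSAKCTEEGKWSPELPVCAP
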