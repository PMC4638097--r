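FGFR3
TP53
PIK3CA
KMT2D
ATM
STAG2
KDM6A
ARID1A
RB1
TSC1
ERBB2
ERCC2
CREBBP
EP300
ELF3
FBXW7
HRAS
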