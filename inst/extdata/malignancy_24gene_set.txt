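CXCL1
EFNA1
TNFSF10
TM4SF1
KRT19
ELF3
KRT13
CCL20
CCND1
KRT18
CDKN2B
SFN
CDKN2A
NDRG1
SERPINB5
KRT17
KRT8
LAD1
SLC2A1
PGK1
PKP1
TGFBI
NEDD4L
GPC1
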