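KRT14
KRT17
KRT6A
KRT5
KRT19
KRT8
KRT16
KRT18
KRT6B
KRT15
KRT6C
KRTCAP3
EPCAM
SFN
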