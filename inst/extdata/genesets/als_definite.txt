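# ALS association tier: Definite (editable curation input)
ANXA11
C9ORF72
FUS
KIF5A
NEK1
OPTN
PFN1
SOD1
TARDBP
TBK1
UBQLN2
VCP
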