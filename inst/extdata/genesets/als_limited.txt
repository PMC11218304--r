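# ALS association tier: Limited (editable curation input)
ANG
ARPP21
C21ORF2/CFAP140
CAV1
CAV2
DAO
ERLIN1
ERLIN2
GLT8D1
KANK1
LGALSL
NEFH
NUP50
PRPH
SS18L1
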