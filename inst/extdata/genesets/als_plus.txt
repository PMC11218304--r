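# ALS association tier: Plus (editable curation input)
AR
CHMP2B
CYLD
DYNC1H1
ERBB4
EWSR1
FIG4
HTT
MAPT
SLC52A2
SLC52A3
SPTLC1
SPTLC2
TAF15
TIA1
hnRNPA1
hnRNPA2B1
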