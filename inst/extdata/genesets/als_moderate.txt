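# ALS association tier: Moderate (editable curation input)
ALS2
ATXN2
CCNF
CHCHD10
DCTN1
DNAJC7
GLE1
GRN
MATR3
SETX
SIGMAR1
SPG11
SQSTM1
TUBA4A
VAPB
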