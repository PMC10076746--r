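symbol	haploinsufficient
ASH1L	1
EP300	1
SCN2A	1
ADNP	1
SHANK3	1
NF1	1
PRKD1	0
PTEN	1
NRXN1	1
TBL1XR1	1
DLG1	1
ELN	0
MYH11	0
GJA5	0
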