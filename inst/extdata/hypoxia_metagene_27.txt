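# hypoxia_metagene_27
ADM
ALDOA
ANLN
ACOT7
CA9
CDKN3
CHCHD2
DDIT4
ENO1
GAPDH
GPI
HILPDA
HK2
LDHA
MCTS1
MIF
MRPS17
NDRG1
P4HA1
PGAM1
PGK1
PSMA7
PSRC1
SLC2A1
TPI1
TUBB6
VEGFA
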