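# stroma_141
COL1A1
COL1A2
COL3A1
COL4A1
COL4A2
COL5A1
COL5A2
COL6A1
COL6A2
COL6A3
COL8A1
COL10A1
COL11A1
COL14A1
COL15A1
COL16A1
COL18A1
FN1
FBN1
FBN2
ELN
EMILIN1
FBLN1
FBLN2
FBLN5
EFEMP1
EFEMP2
LTBP1
LTBP2
LAMA2
LAMA4
LAMB1
LAMC1
NID1
NID2
HSPG2
VCAN
DCN
LUM
BGN
FMOD
OGN
OMD
PRELP
ASPN
POSTN
SPARC
SPARCL1
THBS1
THBS2
THBS4
TNC
TNXB
MGP
MFAP2
MFAP4
MFAP5
CTSK
MMP2
MMP3
MMP11
MMP14
TIMP1
TIMP2
TIMP3
LOX
LOXL1
LOXL2
PLOD1
PLOD2
P4HB
SERPINF1
SERPINH1
PCOLCE
SULF1
GREM1
SFRP2
SFRP4
WISP1
CTGF
CYR61
PDGFRA
PDGFRB
PDGFA
PDGFB
FGF2
FGFR1
TGFB2
TGFB3
TGFBR2
TGFBR3
ACTA2
TAGLN
MYL9
MYH11
CNN1
DES
CALD1
TPM2
LMOD1
PLN
NOTCH3
RGS5
KCNJ8
ABCC9
MCAM
ANGPT1
ANGPT2
TEK
KDR
FLT1
FLT4
VWF
PECAM1
ENG
ESAM
CLDN5
CLEC14A
CD34
CD93
EMCN
RAMP2
RAMP3
ROBO4
TIE1
SOX17
SOX18
ERG
FLI1
LYVE1
CCL14
FAP
PDGFRL
ANTXR1
ISLR
OLFML3
COL12A1
GLT8D2
ITGA11
ADAMTS2
SSC5D
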