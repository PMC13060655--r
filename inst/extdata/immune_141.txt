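# immune_141
CD2
CD3D
CD3E
CD3G
CD247
CD4
CD8A
CD8B
CD19
MS4A1
CD79A
CD79B
CD14
CD68
CD86
CD80
CD28
CTLA4
ICOS
PDCD1
CD274
LAG3
TIGIT
HAVCR2
BTLA
CD27
CD40
CD40LG
TNFRSF9
TNFRSF4
TNFRSF18
GZMA
GZMB
GZMH
GZMK
GZMM
PRF1
GNLY
NKG7
KLRB1
KLRC1
KLRD1
KLRF1
KLRK1
NCR1
NCR3
FCGR3A
FCGR2A
FCGR1A
FCER1G
TYROBP
LCK
ZAP70
LAT
ITK
FYN
SYK
BTK
BLNK
PLCG2
PTPRC
CD52
CD37
CD48
CD53
SASH3
IKZF1
TBX21
EOMES
GATA3
FOXP3
RORC
STAT4
IRF4
IRF8
SPI1
BATF
PRDM1
POU2AF1
CCL2
CCL3
CCL4
CCL5
CCL8
CCL19
CCL21
CCL22
CXCL9
CXCL10
CXCL11
CXCL13
CCR1
CCR2
CCR4
CCR5
CCR7
CXCR3
CXCR4
CXCR5
CXCR6
IL2RA
IL2RB
IL2RG
IL7R
IL10
IL10RA
IL12B
IL15
IL16
IL18
IL21R
IFNG
TNF
LTA
LTB
TGFB1
HLA-A
HLA-B
HLA-C
HLA-DRA
HLA-DRB1
HLA-DPA1
HLA-DPB1
HLA-DQA1
HLA-DQB1
HLA-DMA
HLA-DMB
B2M
TAP1
TAP2
TAPBP
PSMB8
PSMB9
CIITA
NLRC5
AIF1
CSF1R
ITGAM
ITGAX
MRC1
MSR1
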