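ligand	receptor
TGFB1	TGFBR1
TGFB1	TGFBR2
TNF	TNFRSF1A
TNF	TNFRSF1B
IL6	IL6R
IL1B	IL1R1
IL10	IL10RA
IFNG	IFNGR1
EGF	EGFR
TGFA	EGFR
HBEGF	EGFR
VEGFA	FLT1
VEGFA	KDR
PGF	FLT1
FGF2	FGFR1
FGF7	FGFR2
HGF	MET
IGF1	IGF1R
PDGFA	PDGFRA
PDGFB	PDGFRB
CXCL12	CXCR4
CCL2	CCR2
CCL5	CCR5
CX3CL1	CX3CR1
CXCL8	CXCR1
DLL1	NOTCH1
DLL4	NOTCH1
JAG1	NOTCH2
WNT3A	FZD1
WNT5A	FZD5
SHH	PTCH1
EFNB2	EPHB4
SEMA3A	NRP1
NGF	NTRK1
BDNF	NTRK2
CD274	PDCD1
CD80	CTLA4
CD40LG	CD40
FASLG	FAS
ICAM1	ITGAL
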