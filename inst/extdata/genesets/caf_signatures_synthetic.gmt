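iCAF	synthetic placeholder iCAF fibroblast signature (literature-derived marker list)	IL6	CXCL1	CXCL2	CXCL12	CCL2	CFD	PDGFRA	HAS1	HAS2	LMNA	DPT	IGF1	C3	C7	CLU	EFEMP1	MGP	OGN	APOD	GSN
myCAF	synthetic placeholder myCAF fibroblast signature (literature-derived marker list)	TAGLN	MYL9	TPM1	TPM2	MYH11	POSTN	COL12A1	CALD1	CNN1	ACTG2	PDGFRB	THY1	COL5A1	COL6A3	LUM	VCAN	CTHRC1	SPARC	MMP11	FN1
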