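immune_signature_synthetic	synthetic stand-in immune marker set (canonical human immune genes, for demonstration only)	PTPRC	CD3D	CD3E	CD8A	CD2	GZMB	PRF1	NKG7	KLRD1	CD19	MS4A1	CD79A	IL7R	CCL5	CXCL9	CXCL10	IDO1	LCK	ZAP70	TBX21
stromal_signature_synthetic	synthetic stand-in stromal marker set (canonical human stromal genes, for demonstration only)	COL1A1	COL1A2	COL3A1	COL5A1	FAP	PDGFRB	THY1	DCN	LUM	FBLN1	ACTA2	TAGLN	FN1	VCAN	POSTN	SPARC	MMP2	CDH11	COL6A3	THBS2
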