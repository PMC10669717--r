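INSULIN_SIGNALING	Insulin receptor signalling	INS	INSR	IRS1	AKT1	GSK3B	SLC2A4	GCK
NEUROTROPHIN_SIGNALING	Neurotrophin signalling	BDNF	NTRK2	APP	AKT1
ESTROGEN_SIGNALING	Estrogen receptor signalling	ESR1	SP1	RXRA
AMYLOID_PROCESSING	Amyloid precursor protein processing	APP	APOE	LDLR
INFLAMMATION	Inflammatory response	TNF	IL6	CRP	STAT3	NFKB1
ADIPOKINE_SIGNALING	Adipokine signalling	LEP	LEPR	ADIPOQ	ADIPOR1
KATP_CHANNEL	ATP-sensitive potassium channel complex	KCNJ11	ABCC8
AMPK_SIGNALING	AMP-activated protein kinase complex	PRKAA1	PRKAB1
CLATHRIN_ENDOCYTOSIS	Clathrin-mediated endocytosis	AP2M1	CLTC	LDLR
WNT_SIGNALING	Wnt signalling	TCF7L2	CTNNB1
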