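PRKAB1	pp	APP
APP	pp	BDNF
KCNJ11	pp	AP2M1
AP2M1	pp	ESR1
ESR1	pp	BDNF
PRKAB1	pp	IRS1
IRS1	pp	AKT1
AKT1	pp	BDNF
KCNJ11	pp	ABCC8
ABCC8	pp	INS
INS	pp	IGF1R
IGF1R	pp	BDNF
INS	pp	INSR
INSR	pp	IRS1
AKT1	pp	GSK3B
SLC2A4	pp	AKT1
TNF	pp	IL6
IL6	pp	CRP
IL6	pp	STAT3
TNF	pp	NFKB1
LEP	pp	LEPR
ADIPOQ	pp	ADIPOR1
PPARG	pp	RXRA
TCF7L2	pp	CTNNB1
APP	pp	APOE
APOE	pp	LDLR
ESR1	pp	SP1
BDNF	pp	NTRK2
PRKAB1	pp	PRKAA1
AP2M1	pp	CLTC
GCK	pp	INS
HNF4A	pp	GCK
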