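symbol	synonyms	blocked
PRKAB1	AMPK beta 1
APP	amyloid beta precursor protein|amyloid precursor protein
BDNF	brain-derived neurotrophic factor
KCNJ11	Kir6.2
AP2M1	adaptor related protein complex 2 subunit mu 1
ESR1	estrogen receptor alpha
IRS1	insulin receptor substrate 1
AKT1	protein kinase B
ABCC8	SUR1
INS
IGF1R
INSR
GSK3B
SLC2A4	GLUT4
TNF	tumor necrosis factor
IL6	interleukin 6
CRP	C-reactive protein
STAT3
NFKB1
LEP	leptin
LEPR	leptin receptor
ADIPOQ	adiponectin
ADIPOR1
PPARG
RXRA
TCF7L2
CTNNB1	beta-catenin
APOE
LDLR
SP1
NTRK2	TRKB
PRKAA1
CLTC
GCK	glucokinase
HNF4A
GAPDH
CAT	catalase	1
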