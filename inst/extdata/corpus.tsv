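record_id	title	body	year
A01	KATP channel variants and sulfonylurea response	Variants of KCNJ11 and ABCC8 alter sulfonylurea response in T2DM patients.	1998
A01	Duplicate record that must collapse	This duplicated entry of KCNJ11 text should be ignored by curation in T2DM.	1999
A02	Insulin receptor signalling in diabetes	Signalling through INSR and IRS1 is impaired in type 2 diabetes muscle.	2005
A03	Downstream kinases of insulin action	AKT1 and GSK3B regulate SLC2A4 translocation in T2DM adipocytes.	2008
A04	Serum neurotrophin levels in diabetes	Serum BDNF is reduced in T2DM and correlates with cognitive decline.	2015
A05	Sulfonylurea effects on neurotrophin signalling	Glimepiride raises BDNF levels through KCNJ11, AP2M1 and ESR1 in type 2 diabetes.	2021
A06	Biguanide activation of AMP kinase	Metformin activates the PRKAB1 and PRKAA1 subunits of AMP kinase in T2DM liver.	2012
A07	Amyloid biology in metabolic disease	APP processing and APOE genotype influence amyloid burden in diabetes.	2017
A08	Lipoprotein receptors in diabetic dyslipidemia	LDLR and APOE variants modify lipid profiles in T2DM cohorts.	2010
A09	Inflammatory cytokines in diabetes	TNF and IL6 drive chronic inflammation in type 2 diabetes and CRP is elevated.	2007
A10	Cytokine signal transduction	STAT3 and NFKB1 are activated downstream of IL6 in T2DM monocytes.	2013
A11	Leptin axis polymorphisms	LEP and LEPR polymorphisms associate with obesity in T2DM populations.	2004
A12	Adiponectin signalling in insulin resistance	ADIPOQ and ADIPOR1 expression is reduced in diabetes and insulin resistance.	2009
A13	Nuclear receptor agonists	PPARG and RXRA agonists improve insulin sensitivity in T2DM trials.	2006
A14	Common risk alleles for diabetes	TCF7L2 and CTNNB1 variants are the strongest common T2DM risk alleles.	2011
A15	Estrogen receptor transcription	ESR1 cooperates with SP1 to regulate estrogen-responsive genes in diabetes.	2014
A16	Neurotrophin receptor signalling	BDNF signals through NTRK2 to support neuronal survival and is reduced in T2DM.	2018
A17	Clathrin adaptors and transporter endocytosis	AP2M1 and CLTC mediate clathrin endocytosis of glucose transporters in T2DM.	2016
A18	Monogenic forms of diabetes	Mutations in GCK and HNF4A cause monogenic diabetes in young patients.	2002
A19	Beta cell growth factor receptors	INS secretion and IGF1R signalling are altered in beta cells of T2DM donors.	2019
A20	Reference genes for blood expression studies	GAPDH is a stable reference gene for expression studies in T2DM blood.	2020
A21	Linking energy sensing to neurotrophins	APP connects PRKAB1 signalling to BDNF in metabolic disease and T2DM.	2022
A22	Neurotrophins and cognition in aging	Reduced serum BDNF accompanies cognitive impairment in aging adults.	2019
A23	Memory circuits and neurotrophin support	BDNF and NTRK2 support memory consolidation and cognitive function.	2021
X01	Early metabolic studies	Historic insulin balance studies in T2DM wards.	1985
X02	Future perspectives	Projected trends of T2DM care beyond current guidelines.	2025
X03	Pooled evidence on cytokines	A meta-analysis of TNF associations in T2DM cohorts.	2014
X04	Animal neurotrophin work	BDNF changes in a mouse model of diabetes after exercise.	2013
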