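pathway	gene
histone_modification	EP300
histone_modification	CREBBP
histone_modification	KMT2C
histone_modification	KMT2D
histone_modification	KDM6A
histone_modification	BAP1
histone_modification	ASXL1
histone_modification	ASXL2
histone_modification	SETD2
SWI_SNF	ARID1A
SWI_SNF	ARID1B
SWI_SNF	ARID2
DNA_damage	ERCC2
DNA_damage	BRIP1
DNA_damage	ATM
DNA_damage	BRCA1
DNA_damage	BRCA2
DNA_damage	RAD21
DNA_damage	RAD50
DNA_damage	CHEK1
cohesin_complex	STAG1
cohesin_complex	STAG2
cohesin_complex	RAD21
cohesin_complex	SMC1A
cohesin_complex	SMC3
oxidative_stress	NFE2L2
oxidative_stress	KEAP1
oxidative_stress	CUL3
oxidative_stress	TXNIP
alternative_splicing	RBM10
alternative_splicing	SF3B1
alternative_splicing	U2AF1
alternative_splicing	CDK12
RTK_RAS	FGFR3
RTK_RAS	HRAS
RTK_RAS	KRAS
RTK_RAS	NRAS
RTK_RAS	ERBB2
RTK_RAS	ERBB3
RTK_RAS	EGFR
RTK_RAS	NF1
PI3K	PIK3CA
PI3K	PTEN
PI3K	AKT1
PI3K	TSC1
PI3K	TSC2
TP53_pathway	TP53
TP53_pathway	MDM2
TP53_pathway	ATM
cell_cycle	CDKN2A
cell_cycle	CDKN1A
cell_cycle	RB1
cell_cycle	CCND1
cell_cycle	CCNE1
cell_cycle	E2F3
hippo	LATS1
hippo	LATS2
hippo	NF2
hippo	FAT1
myc	MYC
myc	MYCL
myc	MYCN
notch	NOTCH1
notch	NOTCH2
notch	FBXW7
wnt	APC
wnt	CTNNB1
wnt	RNF43
tgf_beta	TGFBR1
tgf_beta	TGFBR2
tgf_beta	SMAD2
tgf_beta	SMAD4
nrf2	NFE2L2
nrf2	KEAP1
nrf2	CUL3
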