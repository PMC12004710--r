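panel	gene
basal	KRT5
basal	KRT6A
basal	KRT14
basal	CD44
basal	KRT16
luminal	KRT20
luminal	GATA3
luminal	FOXA1
luminal	PPARG
luminal	UPK1A
luminal	UPK2
p53	ACTG2
p53	CNN1
p53	MYH11
p53	MFAP4
p53	PGM5
p53	FLNC
p53	DES
stroma	VIM
stroma	ZEB1
stroma	ZEB2
stroma	ACTA2
stroma	PDGFRB
stroma	FAP
stroma	COL1A1
stroma	COL3A1
inflammation	IL6
inflammation	CXCL8
inflammation	TNF
inflammation	IL1B
inflammation	CCL2
inflammation	PTGS2
claudin_low	CLDN3
claudin_low	CLDN4
claudin_low	CLDN7
claudin_low	CDH1
claudin_low	EPCAM
immune_checkpoint	CD274
immune_checkpoint	PDCD1
immune_checkpoint	CTLA4
immune_checkpoint	LAG3
immune_checkpoint	HAVCR2
immune_checkpoint	TIGIT
interferon	STAT1
interferon	IRF1
interferon	GBP1
interferon	CXCL9
interferon	CXCL10
interferon	IDO1
bcg_response	IFNG
bcg_response	GZMB
bcg_response	PRF1
bcg_response	CD8A
bcg_response	GZMA
bcg_response	TBX21
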