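# Genes of special interest per lymphoma subtype group (illustrative curated
# subset: recurrently mutated genes reported for each entity).
subtype	gene
DLBCL	ETV6
DLBCL	RUNX1
DLBCL	PDGFRA
DLBCL	NF1
DLBCL	HIPK3
DLBCL	ITPKB
DLBCL	ENAM
DLBCL	IRF4
DLBCL	RNF213
DLBCL	MYC
DLBCL	FOXO1
DLBCL	KLHL14
DLBCL	OSBPL10
DLBCL	TP53
DLBCL	CREBBP
DLBCL	EZH2
MCL	ATM
MCL	CCND1
MCL	TP53
MCL	KMT2D
MCL	NSD2
MCL	UBR5
MCL	BIRC3
MCL	NOTCH1
MCL	NOTCH2
MCL	SMARCA4
BL	MYC
BL	ID3
BL	TCF3
BL	CCND3
BL	TP53
BL	DDX3X
BL	FOXO1
BL	SMARCA4
T-NHL	STAT1
T-NHL	ZNF708
T-NHL	RHOA
T-NHL	SPEN
T-NHL	FSIP2
T-NHL	DCC
T-NHL	ZNF532
T-NHL	AIRD1B
T-NHL	VPS13A
T-NHL	MYD88
T-NHL	IRF2BP2
T-NHL	VAV1
T-NHL	TCF20
T-NHL	BIRC6
T-NHL	TET2
T-NHL	IDH2
T-NHL	DNMT3A
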