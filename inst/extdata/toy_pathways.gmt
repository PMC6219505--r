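NOTCH_CANONICAL	toy curated set	NOTCH1	RBPJ	HES1	HES5	HEY1	HEY2	JAG2	DLL4	ADAM10	PSEN1	NUMB	LFNG
PI3K_AKT	toy curated set	PIK3CA	PIK3R1	AKT1	AKT2	MTOR	PTEN	INPP4B	PDK1	TSC1	TSC2
CELL_CYCLE	toy curated set	MKI67	CCND1	CCNE1	CDK4	CDK6	RB1	E2F1	TP53	CDKN2A	CDKN1A
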