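macrophage	synthetic_toy_collection	CD163	CD68	CD84	MSR1	MRC1	CSF1R
IFN_downstream	synthetic_toy_collection	STAT1	STAT2	IRF7	MX1	OAS1	ISG15	IFI6	IFIT1
antigen_presentation	synthetic_toy_collection	HLA-A	HLA-B	B2M	TAP1	TAP2	PSMB9
tcell_cytotoxicity	synthetic_toy_collection	CD8A	GZMB	PRF1	IFNG	CD3E	NKG7
cell_cycle	synthetic_toy_collection	MKI67	CCNB1	CDK1	PLK1	TOP2A	BUB1
tgfb_wnt	synthetic_toy_collection	TGFB1	TGFB2	WNT5A	CTNNB1	SMAD3	AXIN2
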