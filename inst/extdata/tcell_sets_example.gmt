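CD4_T_cells	illustrative marker set (synthetic curation, not a published signature)	CD4	IL7R	CD3D	CD3E	CD3G	CD28
CD8_T_cells	illustrative marker set (synthetic curation, not a published signature)	CD8A	CD8B	CD3D	CD3E	GZMK	CD2
Cytotoxic_T_cells	illustrative marker set (synthetic curation, not a published signature)	PRF1	GZMA	GZMB	GNLY	KLRD1	NKG7
T_helper_cells	illustrative marker set (synthetic curation, not a published signature)	CD4	CD28	ICOS	IL2	BATF	STAT4
Tfh_cells	illustrative marker set (synthetic curation, not a published signature)	CXCR5	BCL6	PDCD1	ICOS	IL21	CD200
Th1_cells	illustrative marker set (synthetic curation, not a published signature)	TBX21	IFNG	IL12RB2	STAT1	CXCR3	CCR5
Th1_chemokines	illustrative marker set (synthetic curation, not a published signature)	CXCL9	CXCL10	CXCL11	CCL4	CCL5	CXCR3
Th2_cells	illustrative marker set (synthetic curation, not a published signature)	GATA3	IL4	IL5	IL13	CCR4	STAT6
Th17_cells	illustrative marker set (synthetic curation, not a published signature)	RORC	IL17A	IL17F	IL23R	CCR6	IL22
Treg_cells	illustrative marker set (synthetic curation, not a published signature)	FOXP3	IL2RA	CTLA4	IKZF2	TNFRSF18	CCR8
Naive_CD4_T_cells	illustrative marker set (synthetic curation, not a published signature)	CCR7	SELL	TCF7	LEF1	CD4	IL7R
Naive_CD8_T_cells	illustrative marker set (synthetic curation, not a published signature)	CCR7	SELL	TCF7	LEF1	CD8A	CD8B
Central_memory_CD4_T_cells	illustrative marker set (synthetic curation, not a published signature)	CCR7	SELL	CD4	CD27	CD28	IL7R
Central_memory_CD8_T_cells	illustrative marker set (synthetic curation, not a published signature)	CCR7	SELL	CD8A	CD27	CD28	IL7R
Effector_memory_CD4_T_cells	illustrative marker set (synthetic curation, not a published signature)	CD4	GZMK	CCL5	KLRB1	CD44	PRDM1
Effector_memory_CD8_T_cells	illustrative marker set (synthetic curation, not a published signature)	CD8A	GZMK	GZMH	KLRG1	CX3CR1	EOMES
Gamma_delta_T_cells	illustrative marker set (synthetic curation, not a published signature)	TRGC1	TRGC2	TRDC	KLRC1	KLRD1	NKG7
NKT_cells	illustrative marker set (synthetic curation, not a published signature)	ZBTB16	KLRB1	CD3D	NCAM1	IL18RAP	GZMB
Exhausted_CD8_T_cells	illustrative marker set (synthetic curation, not a published signature)	PDCD1	CTLA4	LAG3	HAVCR2	TIGIT	TOX
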