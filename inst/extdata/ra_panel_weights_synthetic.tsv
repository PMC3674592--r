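snp_id	chromosome	locus_name	risk_allele	other_allele	or
rs11586238	1	CD2/CD58	G	A	1.12
rs12746613	1	FCGR2A	T	C	1.10
rs10910099	1	MMEL1/TNFRSF14	A	G	1.12
rs2476601	1	PTPN22	A	G	1.40
rs10919563	1	PTPRC	G	A	1.11
rs10865035	2	AFF3	G	A	1.12
rs1980422	2	CD28	C	T	1.12
rs3087243	2	CTLA4	G	A	1.13
rs13031237	2	REL	T	G	1.13
rs7574865	2	STAT4	T	G	1.25
rs13315591	3	DNASE1L3/PXK	C	T	1.14
rs6822844	4	IL2/IL21	G	T	1.16
rs874040	4	RBPJ	C	G	1.14
rs26232	5	GIN1/C5orf30	C	T	1.10
rs3093023	6	CCR6	A	G	1.11
rs548234	6	PRDM1	C	T	1.10
rs394581	6	TAGAP	T	C	1.11
rs6920220	6	TNFAIP3 locus 1	A	G	1.22
rs13192841	6	TNFAIP3 locus 2	A	G	1.11
rs5029937	6	TNFAIP3 locus 3	T	G	1.25
rs2736340	8	BLK	C	T	1.12
rs2812378	9	CCL21	G	A	1.10
rs10760130	9	TRAF1/C5	G	A	1.13
rs2104286	10	IL2RA	T	C	1.15
rs4750316	10	PRKCQ	G	C	1.13
rs1678542	12	KIF5A/PIP4K2C	C	G	1.10
rs4810485	20	CD40	T	G	1.14
rs3218258	22	IL2RB	A	G	1.11
rs6910071	6	HLA-DRB1 0401 tag	G	A	2.00
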