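variant_id	chrom	ref	alt	family_id	gene_symbol	transcript_id	consequence_terms	hgvs_c	hgvs_p	mutpred2_mechanisms	pos	exon_index	exon_total	intron_index	intron_total	is_canonical	call_sift	call_polyphen2	call_lrt	call_mutation_taster	call_mutation_assessor	call_fathmm	call_metasvm	call_metalr	call_provean	cadd_phred	gerp	phastcons	phylop	missense_z	mutpred2_score	spliceai_dl	mmsplice	loeuf
22_28725099_T_C	22	T	C	F6	CHEK2	ENST00000404276.6	missense_variant	c.470T>C	p.Ile157Thr	NA	28725099	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	intermediate	tolerated	tolerated	tolerated	23.5	4.6	0.92	5.4	-0.02	NA	NA	NA	NA
10_101583527_G_A	10	G	A	F7	POLL	ENST00000370162.8	missense_variant	c.1046C>T	p.Ala349Val	NA	101583527	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	tolerated	29.1	4.6	0.92	5.4	1.61	NA	NA	NA	NA
12_21486541_G_A	12	G	A	F7	RECQL	ENST00000444129.7	stop_gained	c.439C>T	p.Gln147Ter	Magnesium binding (p=0.036); Amidation (p=0.040)	21486541	4	15	NA	NA	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	38	NA	NA	NA	NA	0.61	NA	NA	1.03
16_46604439_G_A	16	G	A	F7	SHCBP1	ENST00000303383.8	stop_gained	c.712C>T	p.Arg238Ter	NA	46604439	3	12	NA	NA	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	36	NA	NA	NA	NA	0.4	NA	NA	1.02
15_90979162_A_C	15	A	C	F8	PRC1	ENST00000394249.8	missense_variant	c.1103T>G	p.Phe368Cys	NA	90979162	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	intermediate	tolerated	tolerated	tolerated	32	4.6	0.92	5.4	0.76	NA	NA	NA	NA
1_205530350_G_A	1	G	A	F29	CDK18	ENST00000429964.7	splice_donor_variant	c.1312+1G>A	NA	NA	205530350	NA	NA	9	13	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	34	NA	NA	NA	NA	NA	1	-4.034	1.08
2_10128903_C_T	2	C	T	F29	RRM2	ENST00000304567.10	missense_variant	c.854C>T	p.Ser285Leu	NA	10128903	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	tolerated	tolerated	22.9	4.6	0.92	5.4	2.1	NA	NA	NA	NA
19_32976560_C_T	19	C	T	F34	FAAP24	ENST00000588258.6	missense_variant	c.526C>T	p.Leu176Phe	NA	32976560	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	intermediate	tolerated	tolerated	tolerated	26.5	4.6	0.92	5.4	0.97	NA	NA	NA	NA
9_104118330_A_G	9	A	G	F34	SMC2	ENST00000374793.8	missense_variant	c.1951A>G	p.Thr651Ala	NA	104118330	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	intermediate	26.1	4.6	0.92	5.4	0.96	NA	NA	NA	NA
15_89295009_C_T	15	C	T	F36	FANCI	ENST00000310775.12	stop_gained	c.2551C>T	p.Gln851Ter	NA	89295009	25	38	NA	NA	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	43	NA	NA	NA	NA	0.48	NA	NA	0.96
8_6442069_T_TC	8	T	TC	F36	MCPH1	ENST00000344683.10	frameshift_variant	c.586dup	p.Gln196ProfsTer8	Iron binding (p=7.1352e-05); Catalytic site (p=0.0006); Disulfide linkage (p=0.00156); Proteolytic cleavage (p=0.005); Signal helix (p=0.0055)	6442069	5	14	NA	NA	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	25.5	NA	NA	NA	NA	0.32	NA	NA	1.34
17_80425035_C_T	17	C	T	F43	ENDOV	ENST00000518137.6	stop_gained	c.520C>T	p.Arg174Ter	NA	80425035	4	9	NA	NA	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	35	NA	NA	NA	NA	0.42	NA	NA	1.44
11_113736645_C_G	11	C	G	F1_S3	ZW10	ENST00000200135.8	missense_variant	c.2194G>C	p.Ala732Pro	NA	113736645	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	intermediate	tolerated	tolerated	tolerated	27	4.6	0.92	5.4	1.53	NA	NA	NA	NA
1_241889544_G_T	1	G	T	F12_S2	EXO1	ENST00000366548.8	stop_gained	c.2485G>T	p.Glu829Ter	NA	241889544	12	14	NA	NA	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	45	NA	NA	NA	NA	0.5	NA	NA	1.01
17_75660989_T_C	17	T	C	F12_S2	RECQL5	ENST00000317905.10	missense_variant	c.952A>G	p.Ser318Gly	NA	75660989	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	0.75	tolerated	tolerated	27.3	4.6	0.92	5.4	0.6	NA	NA	NA	NA
19_43554680_C_T	19	C	T	F12_S2	XRCC1	ENST00000262887.10	missense_variant	c.380G>A	p.Arg127Gln	NA	43554680	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	tolerated	tolerated	tolerated	tolerated	28	4.6	0.92	5.4	0.56	NA	NA	NA	NA
1_183227656_C_T	1	C	T	F6	LAMC2	ENST00000264144.5	missense_variant	c.1427C>T	p.Thr476Met	NA	183227656	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	intermediate	tolerated	tolerated	23.7	4.6	0.92	5.4	1.35	NA	NA	NA	NA
18_51058218_CTGGT_C	18	CTGGT	C	F6	SMAD4	ENST00000342988.8	frameshift_variant	c.762_765del	p.Gly255SerfsTer80	NA	51058218	6	12	NA	NA	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	29.5	NA	NA	NA	NA	0.69	NA	NA	0.17
6_75102661_G_T	6	G	T	F7	COL12A1	ENST00000322507.13	missense_variant	c.8351C>A	p.Pro2784His	NA	75102661	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	tolerated	tolerated	27	4.6	0.92	5.4	3.55	NA	NA	NA	NA
2_227007353_C_T	2	C	T	F8	COL4A4	ENST00000396625.5	missense_variant	c.5045G>A	p.Arg1682Gln	NA	227007353	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	tolerated	tolerated	27.1	4.6	0.92	5.4	2.22	NA	NA	NA	NA
15_66703558_TGGGAGCTCCCTGCTGGACGTGGCGGAGCC_T	15	TGGGAGCTCCCTGCTGGACGTGGCGGAGCC	T	F8	SMAD6	ENST00000288840.10	frameshift_variant	c.306_334del	p.Ser102ArgfsTer9	NA	66703558	1	4	NA	NA	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	28.3	NA	NA	NA	NA	0.53	NA	NA	2
10_70752124_C_T	10	C	T	F34	ADAMTS14	ENST00000373207.2	missense_variant	c.2626C>T	p.Arg876Cys	NA	70752124	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	intermediate	tolerated	tolerated	29.7	4.6	0.92	5.4	0.79	NA	NA	NA	NA
2_157556276_G_C	2	G	C	F34	ACVR1C	ENST00000243349.13	missense_variant	c.361C>G	p.Pro121Ala	NA	157556276	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	tolerated	tolerated	tolerated	21.5	4.6	0.92	5.4	1.96	NA	NA	NA	NA
7_94427840_C_T	7	C	T	F36	COL1A2	ENST00000297268.11	missense_variant	c.3481C>T	p.Arg1161Cys	NA	94427840	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	tolerated	tolerated	29.5	4.6	0.92	5.4	3.53	NA	NA	NA	NA
17_75756515_C_T	17	C	T	F36	ITGB4	ENST00000200181.8	missense_variant	c.4795C>T	p.Arg1599Cys	NA	75756515	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	intermediate	tolerated	tolerated	tolerated	31	4.6	0.92	5.4	2.17	NA	NA	NA	NA
2_237365895_G_A	2	G	A	F43	COL6A3	ENST00000295550.9	missense_variant	c.5641C>T	p.Arg1881Cys	NA	237365895	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	tolerated	tolerated	tolerated	tolerated	24.6	4.6	0.92	5.4	2.09	NA	NA	NA	NA
7_128840655_G_A	7	G	A	F1_S3	FLNC	ENST00000325888.13	missense_variant	c.1657G>A	p.Gly553Ser	NA	128840655	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	intermediate	29.8	4.6	0.92	5.4	5.95	NA	NA	NA	NA
1_145897010_C_A	1	C	A	F1_S3	ITGA10	ENST00000369304.8	splice_donor_variant	c.2744+1G>T	NA	NA	145897010	NA	NA	22	29	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	24.5	NA	NA	NA	NA	NA	0.94	-6.955	0.83
1_102995999_C_T	1	C	T	F12_S2	COL11A1	ENST00000370096.9	missense_variant	c.2285G>A	p.Arg762Gln	NA	102995999	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	deleterious	tolerated	28.1	4.6	0.92	5.4	1	NA	NA	NA	NA
10_122589066_G_A	10	G	A	F6	DMBT1	ENST00000338354.10	missense_variant	c.1906G>A	p.Ala636Thr	NA	122589066	NA	NA	NA	NA	TRUE	deleterious	deleterious	deleterious	deleterious	deleterious	tolerated	tolerated	tolerated	tolerated	24.8	4.6	0.92	5.4	-0.37	NA	NA	NA	NA
10_122589000_C_T	10	C	T	F34	DMBT1	ENST00000338354.10	stop_gained	c.1840C>T	p.Arg614Ter	Manganese binding (p=0.001); Disulfide linkage (p=0.003); RNA binding (p=0.005); Cadmium binding (p=0.005); Iron binding (p=0.005)	122589000	14	54	NA	NA	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	NA	33	NA	NA	NA	NA	0.5	NA	NA	0.91
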