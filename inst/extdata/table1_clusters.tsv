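cluster_id	gene_count	genes	pathways
Cluster 1	20	CHEK2,EXO1,FAAP24,FANCI,MCPH1,MLH1,MSH2,MSH3,MSH6,MUTYH,NTHL1,PMS2,POLD1,POLE,PRC1,RECQL,RECQL5,RRM2,SHCBP1,SMC2	DNA repair; mismatch repair; base excision repair; mitotic cell cycle
Cluster 2	6	ADAMTS14,COL11A1,COL12A1,COL1A2,COL4A4,COL6A3	ECM-receptor interaction; degradation of ECM; focal adhesion
Cluster 3	4	FLNC,ITGA10,ITGB4,LAMC2	ECM-receptor interaction; focal adhesion
Cluster 4	4	ACVR1C,BMPR1A,SMAD4,SMAD6	TGF-beta signaling pathway
Cluster 16	2	POLL,XRCC1	Base excision repair
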