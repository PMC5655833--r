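gene	protein	accession	ptm	gene_log2_fc	protein_fc	rtt_hit_refs
Mecp2	MeCP2	Q9Z2D6	none	-0.66	-10.6	1,2
Rnpep	RNPEP	Q8VCT3	none	-0.78	-3.47	2
Pdia4	ERp72	P08003	none	-0.71	-2.22	2,3
Hsph1	HSPH1	Q61699	none	-0.80	-2.13	4
Rnpep	RNPEP(Ac)	Q8VCT3	acetyl	-0.78	-2.02	2
Aldh1a1	ALDH1A1	P24549	none	-0.67	-1.95	2
Slc9a3r1	NHERF1(P)	P70441	phospho	-0.74	-1.79	3
Ugt8a	UGT8	Q64676	none	-0.79	-1.76	
Qdpr	QDPR	Q8BVI4	none	-0.74	-1.68	2
Ugp2	UGP2	Q91ZJ5	none	-0.73	-1.67	2
Car2	Ca2	P00920	none	-0.72	-1.61	
Grm3	mGluR3	Q9QYS2	none	-0.63	-1.6	2
Ephx2	EPHX2	P34914	none	-0.71	-1.59	2
Hpcal4	HPCAL4	Q8BGZ1	none	-0.69	-1.51	2,3
Spr	SPR	Q64105	none	-0.77	-1.47	
Sash1	SASH1	P59808	none	-0.82	-1.44	
Calr	CRT	P14211	none	-0.80	-1.43	3
Aacs	AACS	Q9D2R0	none	-0.79	-1.37	2
S1pr1	S1P1	O08530	none	-0.78	-1.28	
Slc9a3r1	NHERF1(Ac)	P70441	acetyl	-0.74	-1.24	3
Nova1	NOVA1	Q9JKN6	none	1.26	1.28	
Slc24a4	Nckx4	Q8CGQ8	none	1.58	1.3	3
Kcnab3	Kvb3.1	P97382	none	1.27	1.43	
Me3	NADP-ME3	Q8BMF3	none	1.28	1.46	
Tfrc	TfR	Q62351	none	1.32	1.48	
Dgkg	DGKg	Q91WG7	none	1.42	1.51	2,3
Prkcg	PKCg(P)	P63318	phospho	-0.82	1.66	3
Rasgrf1	RasGRF1	P27671	none	1.32	1.68	
Zmat4	ZMAT4	Q8BZ94	none	1.50	1.88	3
Myo1b	Myo1b	P46735	none	1.32	2.02	2,3
Fkbp5	FKBP5	Q64378	none	1.81	2.02	2,3,4,5,6
Wipf3	WIPF3	P0C7L0	none	1.23	2.26	
Itih3	ITI-HC3	Q61704	none	1.52	2.37	
Gfra1	GDNFRa1	P97785	none	1.26	2.64	2,3
Sun2	SUN2	Q8BJS4	none	1.42	2.86	3
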