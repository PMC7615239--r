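chr1	18718	19240	VEL1_NV_rep3_site_VEL1_NV_0037	441	.	29.616	46.13	44.061	397
chr1	18777	19248	VEL1_NV_rep3_site_VEL1_NV_0045	469	.	16.014	49.378	46.898	425
chr1	19099	19589	VEL1_NV_rep3_site_VEL1_NV_0032	466	.	8.925	49.348	46.61	362
chr1	24522	25051	VEL1_NV_rep3_site_VEL1_NV_0041	454	.	3.179	48.18	45.419	470
chr1	24932	25175	VEL1_NV_rep3_site_VEL1_NV_0057	197	.	18.53	22.426	19.71	47
chr1	33243	33525	VEL1_NV_rep3_site_VEL1_NV_0039	194	.	7.785	20.691	19.438	199
chr1	40111	40350	VEL1_NV_rep3_site_VEL1_NV_0002	215	.	15.13	25.997	21.46	46
chr1	43708	44007	VEL1_NV_rep3_site_VEL1_NV_0024	222	.	13.541	25.512	22.199	98
chr1	45003	45503	VEL1_NV_rep3_site_VEL1_NV_0031	310	.	4.741	32.801	31.01	50
chr1	51417	51924	VEL1_NV_rep3_site_VEL1_NV_0043	246	.	21.75	27.232	24.581	184
chr1	66619	66908	VEL1_NV_rep3_site_VEL1_NV_0050	274	.	19.673	32.41	27.438	131
chr1	76273	76780	VEL1_NV_rep3_site_VEL1_NV_0017	312	.	28.402	32.334	31.163	432
chr1	83136	83720	VEL1_NV_rep3_site_VEL1_NV_0025	251	.	17.05	29.262	25.076	262
chr1	91085	91419	VEL1_NV_rep3_site_VEL1_NV_0022	291	.	16.305	30.778	29.079	79
chr1	101954	102487	VEL1_NV_rep3_site_VEL1_NV_0046	306	.	21.876	33.848	30.598	515
chr1	102571	102891	VEL1_NV_rep3_site_VEL1_NV_0005	336	.	2.942	35.927	33.599	34
chr1	109168	109478	VEL1_NV_rep3_site_VEL1_NV_0003	490	.	28.172	49.417	48.981	123
chr1	109748	109948	VEL1_NV_rep3_site_VEL1_NV_0019	277	.	7.246	28.829	27.703	143
chr1	119179	119660	VEL1_NV_rep3_site_VEL1_NV_0044	173	.	3.51	17.646	17.307	242
chr1	125042	125555	VEL1_NV_rep3_site_VEL1_NV_0053	148	.	24.781	18.54	14.822	317
chr1	159168	159715	VEL1_NV_rep3_site_VEL1_NV_0051	312	.	6.87	35.692	31.212	488
chr1	165868	166136	VEL1_NV_rep3_site_VEL1_NV_0010	197	.	6.914	21.217	19.658	47
chr1	169767	170186	VEL1_NV_rep3_site_VEL1_NV_0006	227	.	5.748	27.325	22.689	304
chr1	175677	176078	VEL1_NV_rep3_site_VEL1_NV_0018	338	.	29.638	34.196	33.773	219
chr1	175868	176393	VEL1_NV_rep3_site_VEL1_NV_0012	438	.	18.875	45.675	43.755	266
chr1	184253	184729	VEL1_NV_rep3_site_VEL1_NV_0014	245	.	15.4	29.08	24.471	0
chr1	200110	200682	VEL1_NV_rep3_site_VEL1_NV_0036	276	.	14.463	28.077	27.58	114
chr1	200620	200828	VEL1_NV_rep3_site_VEL1_NV_0052	113	.	15.933	12.829	11.263	137
chr1	216797	217252	VEL1_NV_rep3_site_VEL1_NV_0055	382	.	10.078	40.632	38.228	305
chr1	216804	217165	VEL1_NV_rep3_site_VEL1_NV_0008	103	.	7.266	11.341	10.262	297
chr1	218470	219041	VEL1_NV_rep3_site_VEL1_NV_0054	491	.	17.336	50.262	49.092	165
chr1	218748	219281	VEL1_NV_rep3_site_VEL1_NV_0029	400	.	13.001	43.178	39.976	77
chr1	224012	224229	VEL1_NV_rep3_site_VEL1_NV_0007	412	.	20.441	46.121	41.196	96
chr1	238137	238701	VEL1_NV_rep3_site_VEL1_NV_0021	496	.	23.318	50.935	49.554	278
chr1	242037	242396	VEL1_NV_rep3_site_VEL1_NV_0026	200	.	10.182	24.858	20.045	123
chr1	248134	248533	VEL1_NV_rep3_site_VEL1_NV_0059	157	.	23.963	19.25	15.687	149
chr1	248538	248983	VEL1_NV_rep3_site_VEL1_NV_0001	422	.	23.397	44.698	42.18	131
chr1	286278	286837	VEL1_NV_rep3_site_VEL1_NV_0060	165	.	22.953	21.253	16.52	212
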