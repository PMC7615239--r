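chr1	19093	19555	VEL1_NV_rep1_site_VEL1_NV_0032	358	.	5.373	39.482	35.774	368
chr1	19150	19443	VEL1_NV_rep1_site_VEL1_NV_0045	288	.	27.647	31.455	28.803	52
chr1	24606	25204	VEL1_NV_rep1_site_VEL1_NV_0015	343	.	12.803	38.738	34.264	382
chr1	24777	25013	VEL1_NV_rep1_site_VEL1_NV_0057	406	.	20.076	44.071	40.624	202
chr1	24819	25239	VEL1_NV_rep1_site_VEL1_NV_0041	485	.	24.671	49.682	48.516	173
chr1	33293	33671	VEL1_NV_rep1_site_VEL1_NV_0039	192	.	8.89	20.791	19.229	149
chr1	38217	38521	VEL1_NV_rep1_site_VEL1_NV_0027	271	.	12.518	31.748	27.148	252
chr1	43385	43849	VEL1_NV_rep1_site_VEL1_NV_0024	356	.	4.504	40.4	35.584	421
chr1	48106	48312	VEL1_NV_rep1_site_VEL1_NV_0042	225	.	23.3	22.84	22.518	92
chr1	51367	51649	VEL1_NV_rep1_site_VEL1_NV_0043	307	.	28.925	32.471	30.676	234
chr1	66591	67058	VEL1_NV_rep1_site_VEL1_NV_0050	316	.	18.849	35.786	31.559	159
chr1	83336	83563	VEL1_NV_rep1_site_VEL1_NV_0025	433	.	18.638	43.946	43.312	62
chr1	90124	90635	VEL1_NV_rep1_site_VEL1_NV_0033	381	.	8.154	42.678	38.142	179
chr1	102465	102798	VEL1_NV_rep1_site_VEL1_NV_0005	448	.	7.9	46.292	44.844	140
chr1	109171	109395	VEL1_NV_rep1_site_VEL1_NV_0003	168	.	3.87	20.607	16.793	120
chr1	109428	109950	VEL1_NV_rep1_site_VEL1_NV_0019	154	.	11.233	15.919	15.439	463
chr1	119409	119666	VEL1_NV_rep1_site_VEL1_NV_0044	299	.	12.216	30.891	29.897	12
chr1	125050	125456	VEL1_NV_rep1_site_VEL1_NV_0053	127	.	28.958	17.002	12.705	309
chr1	135148	135700	VEL1_NV_rep1_site_VEL1_NV_0058	220	.	22.143	22.781	21.959	34
chr1	145370	145774	VEL1_NV_rep1_site_VEL1_NV_0040	197	.	12.11	20.787	19.687	245
chr1	151617	151911	VEL1_NV_rep1_site_VEL1_NV_0048	151	.	24.394	20.053	15.131	240
chr1	159213	159768	VEL1_NV_rep1_site_VEL1_NV_0051	153	.	16.81	16.718	15.348	443
chr1	165783	166138	VEL1_NV_rep1_site_VEL1_NV_0010	141	.	25.005	18.995	14.109	132
chr1	175807	176281	VEL1_NV_rep1_site_VEL1_NV_0018	334	.	10.491	36.778	33.387	89
chr1	175841	176189	VEL1_NV_rep1_site_VEL1_NV_0012	102	.	13.597	11.762	10.217	293
chr1	200107	200700	VEL1_NV_rep1_site_VEL1_NV_0036	226	.	22.051	27.476	22.648	117
chr1	200583	200911	VEL1_NV_rep1_site_VEL1_NV_0052	256	.	15.468	30.268	25.649	174
chr1	210588	211052	VEL1_NV_rep1_site_VEL1_NV_0034	448	.	5.177	46.15	44.784	204
chr1	216698	217209	VEL1_NV_rep1_site_VEL1_NV_0008	319	.	29.87	32.487	31.865	403
chr1	216934	217423	VEL1_NV_rep1_site_VEL1_NV_0055	122	.	13.941	13.355	12.243	168
chr1	218629	218939	VEL1_NV_rep1_site_VEL1_NV_0054	228	.	3.576	27.201	22.79	6
chr1	223768	224147	VEL1_NV_rep1_site_VEL1_NV_0007	298	.	17.14	33.366	29.818	340
chr1	241827	242208	VEL1_NV_rep1_site_VEL1_NV_0026	405	.	2.861	42.294	40.515	333
chr1	248500	248776	VEL1_NV_rep1_site_VEL1_NV_0001	474	.	9.211	49.602	47.373	169
chr1	251277	251586	VEL1_NV_rep1_site_VEL1_NV_0013	453	.	15.05	49.081	45.262	274
chr1	251490	251698	VEL1_NV_rep1_site_VEL1_NV_0049	149	.	6.799	16.455	14.909	118
chr1	286297	286524	VEL1_NV_rep1_site_VEL1_NV_0060	410	.	12.356	45.469	41.03	193
chr1	293942	294169	VEL1_NV_rep1_site_VEL1_NV_0016	443	.	23.683	47.666	44.326	162
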