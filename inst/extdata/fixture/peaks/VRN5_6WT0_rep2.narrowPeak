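chr1	18471	19049	VRN5_6WT0_rep2_site_VRN5_6WT0_0013	437	.	9	45.421	43.689	476
chr1	43583	43844	VRN5_6WT0_rep2_site_VRN5_6WT0_0033	337	.	22.96	36.191	33.653	111
chr1	43691	44064	VRN5_6WT0_rep2_site_VRN5_6WT0_0036	243	.	15.966	27.484	24.283	369
chr1	49641	49898	VRN5_6WT0_rep2_site_VRN5_6WT0_0037	288	.	25.007	29.713	28.768	112
chr1	49751	50332	VRN5_6WT0_rep2_site_VRN5_6WT0_0001	44	.	28.014	8.188	4.383	415
chr1	51196	51516	VRN5_6WT0_rep2_site_VRN5_6WT0_0018	307	.	12.018	34.173	30.653	200
chr1	74538	74912	VRN5_6WT0_rep2_site_VRN5_6WT0_0020	488	.	12.982	49.384	48.763	127
chr1	76409	76971	VRN5_6WT0_rep2_site_VRN5_6WT0_0031	131	.	9.995	13.08	13.055	547
chr1	85531	86112	VRN5_6WT0_rep2_site_VRN5_6WT0_0019	87	.	17.75	13.45	8.67	493
chr1	125203	125546	VRN5_6WT0_rep2_site_VRN5_6WT0_0022	104	.	11.039	14.372	10.361	99
chr1	145404	145915	VRN5_6WT0_rep2_site_VRN5_6WT0_0026	83	.	13.011	12.823	8.329	83
chr1	145451	145931	VRN5_6WT0_rep2_site_VRN5_6WT0_0002	78	.	29.488	8.835	7.825	331
chr1	151753	152048	VRN5_6WT0_rep2_site_VRN5_6WT0_0016	20	.	8.534	2.835	2.04	252
chr1	153097	153446	VRN5_6WT0_rep2_site_VRN5_6WT0_0044	164	.	18.215	20.142	16.395	184
chr1	159433	159731	VRN5_6WT0_rep2_site_VRN5_6WT0_0047	365	.	3.144	37.197	36.492	256
chr1	159626	159879	VRN5_6WT0_rep2_site_VRN5_6WT0_0043	287	.	16.852	29.845	28.686	189
chr1	161791	162153	VRN5_6WT0_rep2_site_VRN5_6WT0_0030	80	.	11.603	12.112	7.985	63
chr1	167158	167742	VRN5_6WT0_rep2_site_VRN5_6WT0_0007	91	.	25.223	11.113	9.14	310
chr1	169841	170138	VRN5_6WT0_rep2_site_VRN5_6WT0_0039	257	.	11.644	29.182	25.741	94
chr1	172880	173220	VRN5_6WT0_rep2_site_VRN5_6WT0_0012	334	.	4.191	37.646	33.384	62
chr1	179877	180474	VRN5_6WT0_rep2_site_VRN5_6WT0_0035	425	.	11.787	46.777	42.492	26
chr1	181831	182363	VRN5_6WT0_rep2_site_VRN5_6WT0_0034	339	.	28.272	34.528	33.879	150
chr1	186939	187170	VRN5_6WT0_rep2_site_VRN5_6WT0_0027	130	.	2.577	16.699	13.017	139
chr1	192304	192733	VRN5_6WT0_rep2_site_VRN5_6WT0_0023	341	.	14.396	37.785	34.097	420
chr1	192477	192872	VRN5_6WT0_rep2_site_VRN5_6WT0_0040	77	.	27.316	8.979	7.686	162
chr1	194708	195070	VRN5_6WT0_rep2_site_VRN5_6WT0_0014	40	.	16.378	7.485	4.043	274
chr1	202842	203415	VRN5_6WT0_rep2_site_VRN5_6WT0_0004	353	.	29.268	38.803	35.282	131
chr1	203002	203262	VRN5_6WT0_rep2_site_VRN5_6WT0_0038	171	.	13.346	17.874	17.076	60
chr1	210681	211024	VRN5_6WT0_rep2_site_VRN5_6WT0_0005	331	.	10.811	34.1	33.097	171
chr1	214202	214472	VRN5_6WT0_rep2_site_VRN5_6WT0_0021	488	.	23.564	51.196	48.797	212
chr1	216802	217124	VRN5_6WT0_rep2_site_VRN5_6WT0_0032	74	.	6.29	9.65	7.42	211
chr1	218207	218439	VRN5_6WT0_rep2_site_VRN5_6WT0_0041	119	.	11.341	16.683	11.856	223
chr1	226612	226987	VRN5_6WT0_rep2_site_VRN5_6WT0_0042	41	.	14.279	7.248	4.092	3
chr1	233749	234059	VRN5_6WT0_rep2_site_VRN5_6WT0_0045	466	.	19.969	49.974	46.642	307
chr1	242124	242660	VRN5_6WT0_rep2_site_VRN5_6WT0_0011	200	.	11.415	24.972	20.024	372
chr1	242605	242888	VRN5_6WT0_rep2_site_VRN5_6WT0_0003	315	.	14.605	34.098	31.548	241
chr1	257101	257677	VRN5_6WT0_rep2_site_VRN5_6WT0_0010	462	.	13.694	50.535	46.215	450
chr1	258593	259035	VRN5_6WT0_rep2_site_VRN5_6WT0_0046	411	.	27.196	42.286	41.086	246
chr1	259756	260077	VRN5_6WT0_rep2_site_VRN5_6WT0_0024	409	.	16.974	41.613	40.875	57
chr1	277833	278041	VRN5_6WT0_rep2_site_VRN5_6WT0_0008	60	.	26.053	7.179	6.039	3
chr1	283530	283999	VRN5_6WT0_rep2_site_VRN5_6WT0_0006	200	.	4.201	20.58	20.05	238
chr1	291909	292185	VRN5_6WT0_rep2_site_VRN5_6WT0_0025	182	.	15.791	20.036	18.207	6
chr1	293877	294370	VRN5_6WT0_rep2_site_VRN5_6WT0_0017	74	.	5.252	8.33	7.394	47
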