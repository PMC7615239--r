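chr1	18887	19470	VEL1_6WT0_rep3_site_VEL1_6WT0_0015	115	.	21.068	13.598	11.474	196
chr1	43217	43745	VEL1_6WT0_rep3_site_VEL1_6WT0_0041	212	.	10.41	23.102	21.164	490
chr1	43817	44395	VEL1_6WT0_rep3_site_VEL1_6WT0_0044	122	.	26.07	14.831	12.163	242
chr1	49448	49789	VEL1_6WT0_rep3_site_VEL1_6WT0_0045	120	.	10.313	15.591	12.021	286
chr1	49947	50350	VEL1_6WT0_rep3_site_VEL1_6WT0_0001	455	.	24.163	47.261	45.516	236
chr1	50944	51431	VEL1_6WT0_rep3_site_VEL1_6WT0_0020	158	.	15.412	17.235	15.827	433
chr1	55769	56303	VEL1_6WT0_rep3_site_VEL1_6WT0_0030	193	.	19.786	20.559	19.328	351
chr1	74312	74885	VEL1_6WT0_rep3_site_VEL1_6WT0_0023	400	.	11.617	42.87	40.029	336
chr1	76801	77206	VEL1_6WT0_rep3_site_VEL1_6WT0_0039	330	.	11.446	33.605	32.964	241
chr1	85736	86093	VEL1_6WT0_rep3_site_VEL1_6WT0_0021	127	.	3.089	16.634	12.663	231
chr1	92040	92508	VEL1_6WT0_rep3_site_VEL1_6WT0_0013	453	.	2.628	49.307	45.331	283
chr1	118772	119307	VEL1_6WT0_rep3_site_VEL1_6WT0_0037	372	.	7.42	37.792	37.187	456
chr1	125311	125631	VEL1_6WT0_rep3_site_VEL1_6WT0_0025	433	.	11.399	46.26	43.339	26
chr1	145139	145509	VEL1_6WT0_rep3_site_VEL1_6WT0_0032	462	.	28.107	47.789	46.237	366
chr1	145570	145774	VEL1_6WT0_rep3_site_VEL1_6WT0_0002	490	.	23.762	52.537	49.016	170
chr1	151501	152090	VEL1_6WT0_rep3_site_VEL1_6WT0_0018	498	.	2.462	49.914	49.826	486
chr1	153113	153660	VEL1_6WT0_rep3_site_VEL1_6WT0_0052	193	.	11.441	21.5	19.31	226
chr1	159209	159668	VEL1_6WT0_rep3_site_VEL1_6WT0_0028	449	.	29.495	47.072	44.906	164
chr1	159469	159999	VEL1_6WT0_rep3_site_VEL1_6WT0_0051	361	.	16.652	39.573	36.103	345
chr1	159605	159876	VEL1_6WT0_rep3_site_VEL1_6WT0_0055	354	.	23.507	39.419	35.415	65
chr1	161806	162049	VEL1_6WT0_rep3_site_VEL1_6WT0_0038	224	.	23.454	26.625	22.394	38
chr1	167404	167852	VEL1_6WT0_rep3_site_VEL1_6WT0_0007	140	.	25.31	18.322	14.049	73
chr1	179866	180413	VEL1_6WT0_rep3_site_VEL1_6WT0_0043	499	.	26.937	52.375	49.897	54
chr1	186863	187154	VEL1_6WT0_rep3_site_VEL1_6WT0_0033	208	.	26.017	24.955	20.831	259
chr1	192406	192699	VEL1_6WT0_rep3_site_VEL1_6WT0_0048	256	.	3.799	26.326	25.602	233
chr1	192555	192881	VEL1_6WT0_rep3_site_VEL1_6WT0_0027	277	.	10.894	30.877	27.704	116
chr1	194623	195061	VEL1_6WT0_rep3_site_VEL1_6WT0_0016	463	.	20.585	51.043	46.343	303
chr1	202776	203099	VEL1_6WT0_rep3_site_VEL1_6WT0_0004	396	.	29.443	41.257	39.588	170
chr1	203107	203469	VEL1_6WT0_rep3_site_VEL1_6WT0_0046	420	.	2.165	46.591	41.96	3
chr1	210815	211217	VEL1_6WT0_rep3_site_VEL1_6WT0_0005	333	.	5.785	37.064	33.324	9
chr1	216770	216991	VEL1_6WT0_rep3_site_VEL1_6WT0_0040	463	.	21.428	46.916	46.283	205
chr1	218482	218758	VEL1_6WT0_rep3_site_VEL1_6WT0_0049	444	.	29.568	45.915	44.36	36
chr1	222964	223373	VEL1_6WT0_rep3_site_VEL1_6WT0_0022	162	.	17.646	19.392	16.239	252
chr1	233797	234188	VEL1_6WT0_rep3_site_VEL1_6WT0_0053	321	.	9.854	32.576	32.119	218
chr1	242209	242630	VEL1_6WT0_rep3_site_VEL1_6WT0_0012	346	.	13.132	38.193	34.558	271
chr1	242491	243023	VEL1_6WT0_rep3_site_VEL1_6WT0_0003	214	.	10.44	23.291	21.438	414
chr1	283637	283853	VEL1_6WT0_rep3_site_VEL1_6WT0_0006	359	.	19.276	36.944	35.938	198
chr1	285984	286529	VEL1_6WT0_rep3_site_VEL1_6WT0_0036	413	.	13.337	45.577	41.335	196
chr1	293824	294057	VEL1_6WT0_rep3_site_VEL1_6WT0_0019	364	.	11.05	36.511	36.379	70
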