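chr1	18751	19108	VIN3_6WT0_rep1_site_VIN3_6WT0_0012	107	.	26.544	15.083	10.74	316
chr1	23590	24121	VIN3_6WT0_rep1_site_VIN3_6WT0_0007	312	.	4.832	33.39	31.173	9
chr1	43481	43713	VIN3_6WT0_rep1_site_VIN3_6WT0_0033	158	.	17.456	19.81	15.815	175
chr1	43603	44177	VIN3_6WT0_rep1_site_VIN3_6WT0_0036	64	.	20.186	8.006	6.413	457
chr1	49621	50059	VIN3_6WT0_rep1_site_VIN3_6WT0_0037	283	.	10.571	31.084	28.304	57
chr1	49940	50435	VIN3_6WT0_rep1_site_VIN3_6WT0_0001	282	.	20.423	31.508	28.167	217
chr1	50866	51389	VIN3_6WT0_rep1_site_VIN3_6WT0_0016	39	.	29.142	7.672	3.907	496
chr1	74656	74949	VIN3_6WT0_rep1_site_VIN3_6WT0_0018	31	.	4.888	5.891	3.084	23
chr1	76816	77309	VIN3_6WT0_rep1_site_VIN3_6WT0_0031	308	.	7.348	33.867	30.779	242
chr1	85745	86245	VIN3_6WT0_rep1_site_VIN3_6WT0_0017	405	.	5.891	41.652	40.491	225
chr1	91940	92271	VIN3_6WT0_rep1_site_VIN3_6WT0_0011	194	.	9.791	23.952	19.443	269
chr1	125247	125564	VIN3_6WT0_rep1_site_VIN3_6WT0_0020	72	.	7.055	10.461	7.243	14
chr1	145311	145867	VIN3_6WT0_rep1_site_VIN3_6WT0_0002	72	.	5.176	9.648	7.189	433
chr1	151989	152261	VIN3_6WT0_rep1_site_VIN3_6WT0_0014	30	.	26.883	5.765	2.998	6
chr1	153139	153382	VIN3_6WT0_rep1_site_VIN3_6WT0_0042	215	.	7.142	25.787	21.54	216
chr1	159327	159713	VIN3_6WT0_rep1_site_VIN3_6WT0_0023	116	.	15.109	14.874	11.583	72
chr1	159543	159763	VIN3_6WT0_rep1_site_VIN3_6WT0_0045	22	.	5.051	6.085	2.21	37
chr1	161747	162094	VIN3_6WT0_rep1_site_VIN3_6WT0_0030	143	.	4.987	19.174	14.257	50
chr1	167161	167619	VIN3_6WT0_rep1_site_VIN3_6WT0_0006	38	.	10.19	5.912	3.827	348
chr1	169370	169842	VIN3_6WT0_rep1_site_VIN3_6WT0_0021	36	.	28.977	6.937	3.638	248
chr1	169507	169974	VIN3_6WT0_rep1_site_VIN3_6WT0_0039	299	.	26.462	34.354	29.892	424
chr1	179488	179998	VIN3_6WT0_rep1_site_VIN3_6WT0_0035	244	.	23.358	27.657	24.414	454
chr1	181732	182057	VIN3_6WT0_rep1_site_VIN3_6WT0_0034	121	.	15.22	14.046	12.06	76
chr1	187053	187644	VIN3_6WT0_rep1_site_VIN3_6WT0_0027	42	.	11.447	6.711	4.244	61
chr1	194664	195080	VIN3_6WT0_rep1_site_VIN3_6WT0_0008	468	.	3.794	50.796	46.84	265
chr1	194833	195051	VIN3_6WT0_rep1_site_VIN3_6WT0_0013	428	.	22.65	46.265	42.772	47
chr1	203084	203488	VIN3_6WT0_rep1_site_VIN3_6WT0_0038	101	.	7.116	14.675	10.063	69
chr1	210602	210993	VIN3_6WT0_rep1_site_VIN3_6WT0_0005	174	.	19.175	19.28	17.412	203
chr1	214316	214748	VIN3_6WT0_rep1_site_VIN3_6WT0_0019	127	.	12.88	14.345	12.66	146
chr1	216788	217214	VIN3_6WT0_rep1_site_VIN3_6WT0_0032	209	.	24.732	21.796	20.857	132
chr1	218342	218863	VIN3_6WT0_rep1_site_VIN3_6WT0_0040	461	.	18.595	51.021	46.079	231
chr1	233805	234076	VIN3_6WT0_rep1_site_VIN3_6WT0_0043	168	.	29.622	21.29	16.777	168
chr1	242778	243192	VIN3_6WT0_rep1_site_VIN3_6WT0_0003	176	.	9.156	21.972	17.614	126
chr1	257487	257797	VIN3_6WT0_rep1_site_VIN3_6WT0_0009	77	.	5.417	12.589	7.72	95
chr1	258457	258924	VIN3_6WT0_rep1_site_VIN3_6WT0_0044	167	.	7.652	18.298	16.731	340
chr1	259615	259847	VIN3_6WT0_rep1_site_VIN3_6WT0_0024	319	.	2.767	36.038	31.869	196
chr1	286140	286388	VIN3_6WT0_rep1_site_VIN3_6WT0_0028	55	.	11.733	8.64	5.469	93
chr1	291866	292195	VIN3_6WT0_rep1_site_VIN3_6WT0_0026	279	.	7.311	29.63	27.924	185
chr1	293619	293884	VIN3_6WT0_rep1_site_VIN3_6WT0_0015	56	.	28.94	6.063	5.65	263
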