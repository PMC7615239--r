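chr1	19036	19294	VIN3_NV_rep2_site_VIN3_NV_0031	90	.	26.806	12.072	9.029	75
chr1	19279	19806	VIN3_NV_rep2_site_VIN3_NV_0028	216	.	21.869	24.657	21.605	214
chr1	24525	25010	VIN3_NV_rep2_site_VIN3_NV_0014	444	.	14.535	44.577	44.443	471
chr1	24546	25116	VIN3_NV_rep2_site_VIN3_NV_0035	259	.	18.718	30.488	25.857	466
chr1	24803	25057	VIN3_NV_rep2_site_VIN3_NV_0048	66	.	8.628	9.241	6.601	163
chr1	33135	33655	VIN3_NV_rep2_site_VIN3_NV_0033	475	.	2.267	47.851	47.526	230
chr1	33407	33758	VIN3_NV_rep2_site_VIN3_NV_0026	197	.	16.369	19.804	19.744	107
chr1	38425	38685	VIN3_NV_rep2_site_VIN3_NV_0025	165	.	13.914	17.68	16.506	29
chr1	40116	40670	VIN3_NV_rep2_site_VIN3_NV_0002	136	.	4.968	17.015	13.555	74
chr1	43365	43934	VIN3_NV_rep2_site_VIN3_NV_0047	278	.	23.145	30.355	27.825	36
chr1	43370	43697	VIN3_NV_rep2_site_VIN3_NV_0021	31	.	13.099	5.851	3.074	257
chr1	43558	44073	VIN3_NV_rep2_site_VIN3_NV_0022	395	.	17.44	41.759	39.487	359
chr1	51394	51616	VIN3_NV_rep2_site_VIN3_NV_0037	266	.	29.207	30.647	26.555	201
chr1	66570	66798	VIN3_NV_rep2_site_VIN3_NV_0042	58	.	25.439	9.164	5.809	140
chr1	76645	77131	VIN3_NV_rep2_site_VIN3_NV_0016	452	.	9.839	47.314	45.237	19
chr1	83342	83547	VIN3_NV_rep2_site_VIN3_NV_0023	103	.	19.403	11.533	10.251	75
chr1	90174	90696	VIN3_NV_rep2_site_VIN3_NV_0029	434	.	12.832	47.867	43.365	152
chr1	90700	91287	VIN3_NV_rep2_site_VIN3_NV_0020	487	.	13.254	48.776	48.723	526
chr1	102480	102733	VIN3_NV_rep2_site_VIN3_NV_0005	398	.	22.683	42.856	39.811	153
chr1	109141	109681	VIN3_NV_rep2_site_VIN3_NV_0003	398	.	18.207	43.993	39.832	59
chr1	109815	110229	VIN3_NV_rep2_site_VIN3_NV_0018	132	.	11.955	14.579	13.214	100
chr1	119015	119578	VIN3_NV_rep2_site_VIN3_NV_0038	85	.	22.921	8.786	8.506	426
chr1	125091	125563	VIN3_NV_rep2_site_VIN3_NV_0044	140	.	18.976	14.112	13.986	263
chr1	135100	135507	VIN3_NV_rep2_site_VIN3_NV_0049	51	.	26.362	8.558	5.111	0
chr1	145430	145800	VIN3_NV_rep2_site_VIN3_NV_0034	198	.	28.124	24.581	19.77	159
chr1	145578	146148	VIN3_NV_rep2_site_VIN3_NV_0040	172	.	8.79	18.457	17.174	450
chr1	151739	152023	VIN3_NV_rep2_site_VIN3_NV_0041	39	.	23.356	6.78	3.858	94
chr1	159496	159959	VIN3_NV_rep2_site_VIN3_NV_0043	49	.	2.011	5.804	4.889	211
chr1	169770	170142	VIN3_NV_rep2_site_VIN3_NV_0006	141	.	20.673	17.803	14.054	288
chr1	175571	176053	VIN3_NV_rep2_site_VIN3_NV_0017	51	.	19.299	7.963	5.051	352
chr1	175994	176266	VIN3_NV_rep2_site_VIN3_NV_0011	190	.	26.603	23.063	19.042	207
chr1	184194	184522	VIN3_NV_rep2_site_VIN3_NV_0013	175	.	6.629	17.579	17.492	19
chr1	199794	200297	VIN3_NV_rep2_site_VIN3_NV_0030	450	.	4.838	49.385	45.016	495
chr1	216751	217125	VIN3_NV_rep2_site_VIN3_NV_0046	150	.	21.157	15.504	15.028	308
chr1	216796	217379	VIN3_NV_rep2_site_VIN3_NV_0032	94	.	23.018	13.933	9.363	436
chr1	216964	217196	VIN3_NV_rep2_site_VIN3_NV_0010	222	.	24.527	24.023	22.242	52
chr1	218661	218890	VIN3_NV_rep2_site_VIN3_NV_0027	268	.	23.821	29.596	26.833	219
chr1	218665	219117	VIN3_NV_rep2_site_VIN3_NV_0045	464	.	7.133	46.827	46.36	80
chr1	223901	224404	VIN3_NV_rep2_site_VIN3_NV_0004	92	.	7.58	11.213	9.203	54
chr1	238112	238573	VIN3_NV_rep2_site_VIN3_NV_0019	136	.	24.354	17.822	13.603	375
chr1	241784	242379	VIN3_NV_rep2_site_VIN3_NV_0024	82	.	13.999	8.333	8.209	360
chr1	248507	248933	VIN3_NV_rep2_site_VIN3_NV_0001	290	.	13.501	33.514	29.009	144
chr1	251206	251798	VIN3_NV_rep2_site_VIN3_NV_0012	228	.	2.831	25.873	22.841	293
chr1	286116	286478	VIN3_NV_rep2_site_VIN3_NV_0051	266	.	19.118	26.933	26.604	347
chr1	293821	294391	VIN3_NV_rep2_site_VIN3_NV_0015	95	.	11.107	13.502	9.476	335
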