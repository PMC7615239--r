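chr1	18985	19256	VIN3_6WT0_rep2_site_VIN3_6WT0_0012	258	.	7.077	27.673	25.801	82
chr1	23593	23821	VIN3_6WT0_rep2_site_VIN3_6WT0_0007	269	.	15.078	29.683	26.852	6
chr1	43356	43868	VIN3_6WT0_rep2_site_VIN3_6WT0_0033	353	.	15.833	38.976	35.33	300
chr1	43815	44403	VIN3_6WT0_rep2_site_VIN3_6WT0_0036	309	.	4.883	35.181	30.856	245
chr1	51120	51454	VIN3_6WT0_rep2_site_VIN3_6WT0_0016	205	.	26.265	21.979	20.473	242
chr1	55649	56128	VIN3_6WT0_rep2_site_VIN3_6WT0_0025	345	.	10.035	36.514	34.547	442
chr1	74487	74977	VIN3_6WT0_rep2_site_VIN3_6WT0_0018	354	.	27.716	36.009	35.37	192
chr1	76792	77278	VIN3_6WT0_rep2_site_VIN3_6WT0_0031	105	.	15.575	11.169	10.53	266
chr1	85622	86134	VIN3_6WT0_rep2_site_VIN3_6WT0_0017	113	.	11.139	13.691	11.278	348
chr1	92123	92366	VIN3_6WT0_rep2_site_VIN3_6WT0_0011	383	.	20.108	38.405	38.316	86
chr1	119009	119240	VIN3_6WT0_rep2_site_VIN3_6WT0_0029	198	.	23.985	24.257	19.787	195
chr1	124912	125336	VIN3_6WT0_rep2_site_VIN3_6WT0_0020	396	.	12.181	41.306	39.55	349
chr1	159284	159884	VIN3_6WT0_rep2_site_VIN3_6WT0_0023	411	.	27.508	41.72	41.084	115
chr1	161499	161806	VIN3_6WT0_rep2_site_VIN3_6WT0_0030	465	.	17.292	47.454	46.545	298
chr1	167127	167592	VIN3_6WT0_rep2_site_VIN3_6WT0_0006	133	.	19.454	15.728	13.263	382
chr1	179657	180141	VIN3_6WT0_rep2_site_VIN3_6WT0_0035	313	.	18.459	31.426	31.344	285
chr1	181580	181948	VIN3_6WT0_rep2_site_VIN3_6WT0_0034	163	.	26.845	18.983	16.275	228
chr1	187110	187388	VIN3_6WT0_rep2_site_VIN3_6WT0_0027	110	.	25.865	14.152	11.01	4
chr1	192485	192843	VIN3_6WT0_rep2_site_VIN3_6WT0_0022	236	.	22.05	25.922	23.628	217
chr1	202828	203084	VIN3_6WT0_rep2_site_VIN3_6WT0_0004	163	.	9.563	19.039	16.304	73
chr1	203078	203494	VIN3_6WT0_rep2_site_VIN3_6WT0_0038	440	.	6.354	48.291	43.991	75
chr1	210739	211148	VIN3_6WT0_rep2_site_VIN3_6WT0_0005	252	.	12.631	25.84	25.227	66
chr1	216627	217032	VIN3_6WT0_rep2_site_VIN3_6WT0_0032	269	.	2.476	30.775	26.89	293
chr1	218248	218814	VIN3_6WT0_rep2_site_VIN3_6WT0_0040	127	.	4.082	15.765	12.659	325
chr1	233930	234415	VIN3_6WT0_rep2_site_VIN3_6WT0_0043	110	.	6.712	11.838	11.008	43
chr1	242671	243045	VIN3_6WT0_rep2_site_VIN3_6WT0_0003	213	.	16.5	26.114	21.277	233
chr1	257052	257609	VIN3_6WT0_rep2_site_VIN3_6WT0_0009	261	.	6.458	29.573	26.056	530
chr1	258674	259256	VIN3_6WT0_rep2_site_VIN3_6WT0_0044	291	.	17.138	30.725	29.13	123
chr1	259564	259855	VIN3_6WT0_rep2_site_VIN3_6WT0_0024	247	.	23.755	25.208	24.682	247
chr1	285986	286257	VIN3_6WT0_rep2_site_VIN3_6WT0_0028	458	.	23.728	49.015	45.771	247
chr1	291989	292355	VIN3_6WT0_rep2_site_VIN3_6WT0_0026	160	.	23.56	20.371	15.954	62
chr1	293778	294129	VIN3_6WT0_rep2_site_VIN3_6WT0_0015	324	.	16.718	33.59	32.369	104
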