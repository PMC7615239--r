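chr1	18854	19071	VIN3_6WT0_rep3_site_VIN3_6WT0_0012	396	.	25.313	39.931	39.641	213
chr1	23563	23780	VIN3_6WT0_rep3_site_VIN3_6WT0_0007	367	.	17.919	38.295	36.666	36
chr1	43999	44336	VIN3_6WT0_rep3_site_VIN3_6WT0_0036	465	.	28.628	51.052	46.501	61
chr1	50096	50587	VIN3_6WT0_rep3_site_VIN3_6WT0_0001	397	.	13.054	41.383	39.656	61
chr1	51342	51922	VIN3_6WT0_rep3_site_VIN3_6WT0_0016	345	.	16.065	34.983	34.49	20
chr1	74566	74976	VIN3_6WT0_rep3_site_VIN3_6WT0_0018	485	.	27.39	48.732	48.53	113
chr1	85631	86202	VIN3_6WT0_rep3_site_VIN3_6WT0_0017	143	.	7.635	15.338	14.271	339
chr1	118966	119237	VIN3_6WT0_rep3_site_VIN3_6WT0_0029	241	.	22.503	25.723	24.1	238
chr1	145550	146092	VIN3_6WT0_rep3_site_VIN3_6WT0_0002	290	.	3.25	33.781	29.046	194
chr1	153228	153509	VIN3_6WT0_rep3_site_VIN3_6WT0_0042	378	.	17.688	40.523	37.817	127
chr1	161593	161904	VIN3_6WT0_rep3_site_VIN3_6WT0_0030	135	.	11.146	16.231	13.503	204
chr1	169573	169787	VIN3_6WT0_rep3_site_VIN3_6WT0_0021	256	.	10.436	28.485	25.628	45
chr1	169655	170043	VIN3_6WT0_rep3_site_VIN3_6WT0_0039	379	.	5.809	39.853	37.887	276
chr1	181458	181826	VIN3_6WT0_rep3_site_VIN3_6WT0_0034	496	.	23.486	50.464	49.577	350
chr1	194719	195087	VIN3_6WT0_rep3_site_VIN3_6WT0_0013	448	.	12.084	46.749	44.762	161
chr1	214025	214522	VIN3_6WT0_rep3_site_VIN3_6WT0_0019	249	.	29.426	29.764	24.916	437
chr1	216852	217333	VIN3_6WT0_rep3_site_VIN3_6WT0_0032	320	.	4.275	33.452	32.024	68
chr1	218536	218848	VIN3_6WT0_rep3_site_VIN3_6WT0_0040	436	.	4.886	43.816	43.638	37
chr1	242279	242837	VIN3_6WT0_rep3_site_VIN3_6WT0_0010	348	.	26.665	37.495	34.773	154
chr1	242742	243160	VIN3_6WT0_rep3_site_VIN3_6WT0_0003	287	.	12.615	33.595	28.664	162
chr1	258535	259091	VIN3_6WT0_rep3_site_VIN3_6WT0_0044	177	.	6.324	22.138	17.701	262
chr1	286027	286342	VIN3_6WT0_rep3_site_VIN3_6WT0_0028	450	.	12.433	47.705	44.993	206
chr1	293782	294203	VIN3_6WT0_rep3_site_VIN3_6WT0_0015	124	.	27.077	16.065	12.353	100
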