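chr1	19052	19366	VIN3_NV_rep1_site_VIN3_NV_0031	349	.	10.751	38.15	34.858	59
chr1	19308	19694	VIN3_NV_rep1_site_VIN3_NV_0028	315	.	19.567	32.387	31.537	185
chr1	24426	24999	VIN3_NV_rep1_site_VIN3_NV_0048	153	.	14.35	16.675	15.268	540
chr1	24826	25082	VIN3_NV_rep1_site_VIN3_NV_0035	280	.	12.401	31.61	28.012	186
chr1	33209	33421	VIN3_NV_rep1_site_VIN3_NV_0033	394	.	26.857	40.157	39.4	156
chr1	43351	43659	VIN3_NV_rep1_site_VIN3_NV_0021	271	.	27.994	29.589	27.054	276
chr1	48140	48380	VIN3_NV_rep1_site_VIN3_NV_0036	306	.	19.828	33.456	30.561	38
chr1	51288	51612	VIN3_NV_rep1_site_VIN3_NV_0037	250	.	24.974	26.757	25.036	307
chr1	91053	91263	VIN3_NV_rep1_site_VIN3_NV_0020	275	.	24.503	29.954	27.544	173
chr1	102249	102547	VIN3_NV_rep1_site_VIN3_NV_0039	203	.	12.62	22.816	20.326	124
chr1	102552	102768	VIN3_NV_rep1_site_VIN3_NV_0005	399	.	16.213	40.889	39.889	81
chr1	135001	135449	VIN3_NV_rep1_site_VIN3_NV_0049	242	.	8.49	26.487	24.225	99
chr1	145986	146309	VIN3_NV_rep1_site_VIN3_NV_0040	129	.	12.165	15.561	12.858	42
chr1	151555	152014	VIN3_NV_rep1_site_VIN3_NV_0041	213	.	15.504	25.409	21.307	278
chr1	175844	176423	VIN3_NV_rep1_site_VIN3_NV_0017	355	.	28.376	36.636	35.483	79
chr1	175917	176289	VIN3_NV_rep1_site_VIN3_NV_0011	379	.	9.026	39.956	37.94	284
chr1	184034	184381	VIN3_NV_rep1_site_VIN3_NV_0013	265	.	4.835	29.007	26.459	179
chr1	200208	200771	VIN3_NV_rep1_site_VIN3_NV_0030	174	.	18.817	18.326	17.404	81
chr1	216482	217079	VIN3_NV_rep1_site_VIN3_NV_0010	178	.	28.011	21.496	17.793	534
chr1	217008	217210	VIN3_NV_rep1_site_VIN3_NV_0046	229	.	28.348	23.269	22.869	51
chr1	217047	217590	VIN3_NV_rep1_site_VIN3_NV_0032	269	.	6.863	30.99	26.889	185
chr1	218631	219201	VIN3_NV_rep1_site_VIN3_NV_0045	287	.	24.016	30.251	28.71	114
chr1	218802	219395	VIN3_NV_rep1_site_VIN3_NV_0027	130	.	18.062	16.853	12.991	78
chr1	223864	224142	VIN3_NV_rep1_site_VIN3_NV_0004	355	.	9.798	36.015	35.538	91
chr1	241944	242315	VIN3_NV_rep1_site_VIN3_NV_0024	427	.	19.868	43.196	42.705	200
chr1	251205	251575	VIN3_NV_rep1_site_VIN3_NV_0012	465	.	8.009	47.143	46.478	294
chr1	286168	286512	VIN3_NV_rep1_site_VIN3_NV_0051	218	.	23.176	26.101	21.791	295
chr1	294050	294494	VIN3_NV_rep1_site_VIN3_NV_0015	195	.	26.244	22.968	19.53	106
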