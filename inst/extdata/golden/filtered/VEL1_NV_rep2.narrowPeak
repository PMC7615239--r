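chr1	18981	19558	VEL1_NV_rep2_site_VEL1_NV_0037	259	.	17.111	28.78	25.897	134
chr1	19185	19714	VEL1_NV_rep2_site_VEL1_NV_0032	178	.	4.44	20.085	17.844	276
chr1	19188	19643	VEL1_NV_rep2_site_VEL1_NV_0045	312	.	18.99	35.483	31.187	14
chr1	24594	25018	VEL1_NV_rep2_site_VEL1_NV_0041	273	.	28.315	31.959	27.277	398
chr1	24767	25061	VEL1_NV_rep2_site_VEL1_NV_0057	289	.	22.617	32.848	28.886	212
chr1	24972	25489	VEL1_NV_rep2_site_VEL1_NV_0015	397	.	25.223	42.094	39.686	16
chr1	33352	33807	VEL1_NV_rep2_site_VEL1_NV_0028	409	.	22.667	44.317	40.904	163
chr1	38264	38807	VEL1_NV_rep2_site_VEL1_NV_0027	123	.	28.62	16.536	12.256	205
chr1	39880	40175	VEL1_NV_rep2_site_VEL1_NV_0002	464	.	4.588	49.602	46.372	277
chr1	43264	43764	VEL1_NV_rep2_site_VEL1_NV_0056	464	.	4.641	49.452	46.356	68
chr1	43408	43997	VEL1_NV_rep2_site_VEL1_NV_0030	143	.	25.356	15.047	14.266	342
chr1	43671	44111	VEL1_NV_rep2_site_VEL1_NV_0024	237	.	3.745	24.469	23.696	135
chr1	47991	48351	VEL1_NV_rep2_site_VEL1_NV_0042	192	.	12.909	22.386	19.24	207
chr1	66696	67115	VEL1_NV_rep2_site_VEL1_NV_0050	249	.	22.021	29.682	24.904	54
chr1	90253	90830	VEL1_NV_rep2_site_VEL1_NV_0033	120	.	20.567	14.804	12.025	50
chr1	102497	102931	VEL1_NV_rep2_site_VEL1_NV_0005	366	.	14.964	39.603	36.583	108
chr1	119369	119785	VEL1_NV_rep2_site_VEL1_NV_0044	445	.	2.889	48.56	44.509	52
chr1	125139	125684	VEL1_NV_rep2_site_VEL1_NV_0053	351	.	26.602	38.466	35.148	220
chr1	134753	135209	VEL1_NV_rep2_site_VEL1_NV_0058	230	.	3.519	25.746	23.046	429
chr1	145161	145658	VEL1_NV_rep2_site_VEL1_NV_0040	339	.	10.708	35.605	33.876	454
chr1	170051	170270	VEL1_NV_rep2_site_VEL1_NV_0006	301	.	11.972	32.224	30.118	20
chr1	175767	176271	VEL1_NV_rep2_site_VEL1_NV_0018	250	.	22.434	28.024	24.963	129
chr1	176097	176340	VEL1_NV_rep2_site_VEL1_NV_0012	149	.	7.953	17.335	14.894	37
chr1	184121	184496	VEL1_NV_rep2_site_VEL1_NV_0014	384	.	29.531	41.71	38.441	132
chr1	200069	200290	VEL1_NV_rep2_site_VEL1_NV_0036	146	.	17.758	18.088	14.583	155
chr1	216700	217164	VEL1_NV_rep2_site_VEL1_NV_0011	138	.	5.955	16.097	13.803	233
chr1	217082	217328	VEL1_NV_rep2_site_VEL1_NV_0055	453	.	29.069	48.099	45.346	20
chr1	217206	217745	VEL1_NV_rep2_site_VEL1_NV_0038	358	.	12.526	40.499	35.771	2
chr1	218479	218908	VEL1_NV_rep2_site_VEL1_NV_0054	284	.	16.404	29.899	28.448	156
chr1	218705	218956	VEL1_NV_rep2_site_VEL1_NV_0029	323	.	27.855	32.742	32.268	120
chr1	223870	224272	VEL1_NV_rep2_site_VEL1_NV_0007	462	.	20.24	47.998	46.201	238
chr1	238090	238425	VEL1_NV_rep2_site_VEL1_NV_0021	366	.	13.427	37.655	36.557	325
chr1	241801	242207	VEL1_NV_rep2_site_VEL1_NV_0026	496	.	24.928	54.008	49.553	359
chr1	248181	248504	VEL1_NV_rep2_site_VEL1_NV_0059	419	.	27.169	43.82	41.87	102
chr1	250983	251566	VEL1_NV_rep2_site_VEL1_NV_0013	203	.	19.589	23.283	20.309	568
chr1	251423	251834	VEL1_NV_rep2_site_VEL1_NV_0049	102	.	23.348	14.318	10.195	185
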