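chr1	18768	19239	VRN5_6WT0_rep1_site_VRN5_6WT0_0013	263	.	2.214	30.502	26.292	179
chr1	43517	43751	VRN5_6WT0_rep1_site_VRN5_6WT0_0033	185	.	25.88	19.924	18.485	177
chr1	51205	51758	VRN5_6WT0_rep1_site_VRN5_6WT0_0018	345	.	7.956	35.143	34.456	191
chr1	74510	75093	VRN5_6WT0_rep1_site_VRN5_6WT0_0020	261	.	15.77	30.815	26.103	155
chr1	76769	77017	VRN5_6WT0_rep1_site_VRN5_6WT0_0031	173	.	26.04	17.729	17.313	187
chr1	85890	86486	VRN5_6WT0_rep1_site_VRN5_6WT0_0019	140	.	12.799	15.761	13.98	134
chr1	106863	107164	VRN5_6WT0_rep1_site_VRN5_6WT0_0015	325	.	25.574	34.868	32.489	241
chr1	119056	119260	VRN5_6WT0_rep1_site_VRN5_6WT0_0029	174	.	20.501	18.061	17.353	173
chr1	125115	125516	VRN5_6WT0_rep1_site_VRN5_6WT0_0022	278	.	24.273	28.775	27.82	187
chr1	145461	145988	VRN5_6WT0_rep1_site_VRN5_6WT0_0026	444	.	29.658	48.413	44.443	26
chr1	145733	146046	VRN5_6WT0_rep1_site_VRN5_6WT0_0002	354	.	26.541	36.532	35.449	49
chr1	159778	160009	VRN5_6WT0_rep1_site_VRN5_6WT0_0043	389	.	21.484	40.762	38.947	37
chr1	161722	162061	VRN5_6WT0_rep1_site_VRN5_6WT0_0030	123	.	6.922	16.876	12.343	132
chr1	167067	167469	VRN5_6WT0_rep1_site_VRN5_6WT0_0007	464	.	17.198	50.262	46.449	401
chr1	179760	179984	VRN5_6WT0_rep1_site_VRN5_6WT0_0035	164	.	10.083	18.59	16.36	143
chr1	187029	187265	VRN5_6WT0_rep1_site_VRN5_6WT0_0027	169	.	29.584	19.633	16.857	49
chr1	192404	192735	VRN5_6WT0_rep1_site_VRN5_6WT0_0040	140	.	5.76	14.738	14.022	235
chr1	192435	192783	VRN5_6WT0_rep1_site_VRN5_6WT0_0023	182	.	21.28	19.79	18.193	289
chr1	194924	195216	VRN5_6WT0_rep1_site_VRN5_6WT0_0014	134	.	19.765	17.466	13.379	58
chr1	202632	203124	VRN5_6WT0_rep1_site_VRN5_6WT0_0038	241	.	24.261	27.114	24.093	430
chr1	216720	217137	VRN5_6WT0_rep1_site_VRN5_6WT0_0032	123	.	17.749	15.971	12.265	293
chr1	218279	218696	VRN5_6WT0_rep1_site_VRN5_6WT0_0041	425	.	15.847	45.086	42.524	151
chr1	234034	234234	VRN5_6WT0_rep1_site_VRN5_6WT0_0045	303	.	2.771	33.474	30.337	22
chr1	242267	242655	VRN5_6WT0_rep1_site_VRN5_6WT0_0011	480	.	11.323	52.574	48.007	229
chr1	242674	243017	VRN5_6WT0_rep1_site_VRN5_6WT0_0003	434	.	24.834	45.589	43.412	172
chr1	259466	259886	VRN5_6WT0_rep1_site_VRN5_6WT0_0024	104	.	14.342	13.852	10.387	347
chr1	277836	278087	VRN5_6WT0_rep1_site_VRN5_6WT0_0008	166	.	12.758	20.81	16.639	0
chr1	291616	292128	VRN5_6WT0_rep1_site_VRN5_6WT0_0025	326	.	8.721	37.348	32.644	299
chr1	293917	294175	VRN5_6WT0_rep1_site_VRN5_6WT0_0017	459	.	5.214	46.307	45.859	7
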