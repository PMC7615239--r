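chr1	19315	19684	VRN5_NV_rep3_site_VRN5_NV_0021	206	.	9.418	20.934	20.637	192
chr1	24727	25061	VRN5_NV_rep3_site_VRN5_NV_0042	223	.	7.702	24.802	22.298	178
chr1	24878	25182	VRN5_NV_rep3_site_VRN5_NV_0009	308	.	12.634	35.209	30.764	194
chr1	33323	33829	VRN5_NV_rep3_site_VRN5_NV_0027	405	.	4.073	44.229	40.529	204
chr1	33379	33872	VRN5_NV_rep3_site_VRN5_NV_0017	434	.	29.661	48.362	43.379	197
chr1	45033	45469	VRN5_NV_rep3_site_VRN5_NV_0020	377	.	29.102	39.58	37.722	43
chr1	47935	48246	VRN5_NV_rep3_site_VRN5_NV_0030	466	.	11.048	50.243	46.593	208
chr1	51271	51827	VRN5_NV_rep3_site_VRN5_NV_0031	486	.	6.396	49.202	48.581	320
chr1	76419	76733	VRN5_NV_rep3_site_VRN5_NV_0011	363	.	22.689	38.066	36.252	290
chr1	83199	83548	VRN5_NV_rep3_site_VRN5_NV_0015	154	.	18.366	19.92	15.44	219
chr1	102098	102698	VRN5_NV_rep3_site_VRN5_NV_0033	495	.	3.009	53.313	49.481	278
chr1	125202	125419	VRN5_NV_rep3_site_VRN5_NV_0038	374	.	10.594	38.352	37.435	104
chr1	135113	135531	VRN5_NV_rep3_site_VRN5_NV_0043	405	.	19.174	41.858	40.456	17
chr1	145206	145773	VRN5_NV_rep3_site_VRN5_NV_0028	266	.	23.91	30.721	26.551	319
chr1	146119	146581	VRN5_NV_rep3_site_VRN5_NV_0034	123	.	3.976	12.5	12.329	4
chr1	175895	176331	VRN5_NV_rep3_site_VRN5_NV_0006	421	.	10.456	43.661	42.067	284
chr1	183864	184296	VRN5_NV_rep3_site_VRN5_NV_0008	435	.	4.524	47.189	43.536	348
chr1	210303	210878	VRN5_NV_rep3_site_VRN5_NV_0023	439	.	12.731	46.475	43.949	453
chr1	216750	217144	VRN5_NV_rep3_site_VRN5_NV_0003	237	.	4.974	25.228	23.676	368
chr1	216776	217008	VRN5_NV_rep3_site_VRN5_NV_0005	263	.	14.746	30.544	26.292	156
chr1	216952	217228	VRN5_NV_rep3_site_VRN5_NV_0040	472	.	22.272	51.451	47.196	112
chr1	218528	219115	VRN5_NV_rep3_site_VRN5_NV_0018	426	.	10.829	45.68	42.631	395
chr1	218611	218939	VRN5_NV_rep3_site_VRN5_NV_0039	443	.	29.73	47.376	44.318	34
chr1	251316	251899	VRN5_NV_rep3_site_VRN5_NV_0036	475	.	3.59	49.366	47.542	294
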