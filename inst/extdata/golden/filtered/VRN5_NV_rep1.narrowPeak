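chr1	19057	19483	VRN5_NV_rep1_site_VRN5_NV_0025	248	.	23.259	28.631	24.818	44
chr1	19480	19872	VRN5_NV_rep1_site_VRN5_NV_0021	449	.	12.089	49.604	44.925	27
chr1	24622	25112	VRN5_NV_rep1_site_VRN5_NV_0029	398	.	20.354	40.011	39.848	352
chr1	24747	25305	VRN5_NV_rep1_site_VRN5_NV_0042	327	.	3.266	37.513	32.665	158
chr1	25013	25483	VRN5_NV_rep1_site_VRN5_NV_0009	330	.	15.479	36.122	33.03	59
chr1	33510	33809	VRN5_NV_rep1_site_VRN5_NV_0017	251	.	20.685	26.605	25.118	66
chr1	43553	43999	VRN5_NV_rep1_site_VRN5_NV_0019	413	.	29.2	42.061	41.259	253
chr1	44595	45182	VRN5_NV_rep1_site_VRN5_NV_0020	322	.	25.827	36.451	32.222	481
chr1	48086	48651	VRN5_NV_rep1_site_VRN5_NV_0030	464	.	26.639	50.921	46.405	57
chr1	76458	76845	VRN5_NV_rep1_site_VRN5_NV_0011	420	.	9.33	43.619	42.032	251
chr1	90315	90603	VRN5_NV_rep1_site_VRN5_NV_0022	439	.	20.258	44.241	43.881	11
chr1	102190	102608	VRN5_NV_rep1_site_VRN5_NV_0033	330	.	13.424	33.388	33.039	186
chr1	109860	110105	VRN5_NV_rep1_site_VRN5_NV_0012	269	.	20.77	29.156	26.938	98
chr1	119354	119845	VRN5_NV_rep1_site_VRN5_NV_0032	416	.	25.862	43.775	41.557	80
chr1	125001	125490	VRN5_NV_rep1_site_VRN5_NV_0038	132	.	13.427	18.008	13.223	305
chr1	134970	135520	VRN5_NV_rep1_site_VRN5_NV_0043	270	.	29.09	31.577	27.026	160
chr1	145329	145676	VRN5_NV_rep1_site_VRN5_NV_0028	160	.	24.723	18.951	16	196
chr1	151563	151917	VRN5_NV_rep1_site_VRN5_NV_0035	497	.	8.283	50.008	49.706	284
chr1	165871	166120	VRN5_NV_rep1_site_VRN5_NV_0004	228	.	18.691	23.481	22.767	129
chr1	184144	184400	VRN5_NV_rep1_site_VRN5_NV_0008	372	.	13.149	38.857	37.19	68
chr1	200476	200889	VRN5_NV_rep1_site_VRN5_NV_0037	123	.	25.88	14.262	12.328	344
chr1	216887	217204	VRN5_NV_rep1_site_VRN5_NV_0040	228	.	5.963	26.752	22.784	177
chr1	216941	217329	VRN5_NV_rep1_site_VRN5_NV_0026	207	.	4.698	21.743	20.721	277
chr1	217001	217523	VRN5_NV_rep1_site_VRN5_NV_0003	304	.	16.931	31.71	30.36	117
chr1	251318	251854	VRN5_NV_rep1_site_VRN5_NV_0007	211	.	20.724	21.26	21.104	248
chr1	286512	286874	VRN5_NV_rep1_site_VRN5_NV_0045	430	.	6.292	44.19	42.989	36
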