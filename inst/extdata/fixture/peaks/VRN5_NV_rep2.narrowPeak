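chr1	19032	19276	VRN5_NV_rep2_site_VRN5_NV_0025	26	.	9.044	5.766	2.583	69
chr1	19449	20011	VRN5_NV_rep2_site_VRN5_NV_0021	355	.	27.915	37.168	35.53	58
chr1	24604	24930	VRN5_NV_rep2_site_VRN5_NV_0042	58	.	23.462	6.387	5.769	301
chr1	24884	25247	VRN5_NV_rep2_site_VRN5_NV_0009	191	.	2.579	22.348	19.065	188
chr1	24951	25328	VRN5_NV_rep2_site_VRN5_NV_0029	216	.	7.446	26.088	21.595	23
chr1	33318	33702	VRN5_NV_rep2_site_VRN5_NV_0027	91	.	9.515	9.539	9.061	209
chr1	33414	33700	VRN5_NV_rep2_site_VRN5_NV_0017	35	.	6.254	6.621	3.488	162
chr1	38281	38779	VRN5_NV_rep2_site_VRN5_NV_0016	404	.	3.888	41.392	40.393	205
chr1	43259	43512	VRN5_NV_rep2_site_VRN5_NV_0041	27	.	25.652	3.777	2.668	88
chr1	43424	43839	VRN5_NV_rep2_site_VRN5_NV_0014	143	.	7.596	17.795	14.3	303
chr1	43715	44164	VRN5_NV_rep2_site_VRN5_NV_0019	62	.	6.748	7.687	6.22	91
chr1	44880	45448	VRN5_NV_rep2_site_VRN5_NV_0020	88	.	8.237	11.559	8.77	196
chr1	48086	48499	VRN5_NV_rep2_site_VRN5_NV_0030	413	.	16.23	45.524	41.285	57
chr1	76534	76761	VRN5_NV_rep2_site_VRN5_NV_0011	304	.	4.762	34.244	30.377	175
chr1	83193	83434	VRN5_NV_rep2_site_VRN5_NV_0015	485	.	25.314	49.329	48.506	225
chr1	90051	90385	VRN5_NV_rep2_site_VRN5_NV_0022	151	.	5.641	15.102	15.073	275
chr1	102058	102636	VRN5_NV_rep2_site_VRN5_NV_0033	27	.	4.513	4.035	2.731	318
chr1	125066	125330	VRN5_NV_rep2_site_VRN5_NV_0038	152	.	7.788	17.832	15.165	240
chr1	134660	134981	VRN5_NV_rep2_site_VRN5_NV_0024	402	.	23.954	42.342	40.151	134
chr1	135043	135494	VRN5_NV_rep2_site_VRN5_NV_0043	264	.	22.152	27.148	26.425	87
chr1	145464	145837	VRN5_NV_rep2_site_VRN5_NV_0028	31	.	6.148	6.876	3.106	61
chr1	145807	146372	VRN5_NV_rep2_site_VRN5_NV_0034	79	.	23.271	9.205	7.907	316
chr1	151705	152102	VRN5_NV_rep2_site_VRN5_NV_0035	98	.	17.911	14.06	9.783	142
chr1	165936	166496	VRN5_NV_rep2_site_VRN5_NV_0004	469	.	15.519	49.785	46.907	64
chr1	176176	176639	VRN5_NV_rep2_site_VRN5_NV_0006	405	.	16.99	42.515	40.455	3
chr1	200344	200871	VRN5_NV_rep2_site_VRN5_NV_0037	24	.	5.799	3.132	2.415	476
chr1	210704	210976	VRN5_NV_rep2_site_VRN5_NV_0023	401	.	17.242	43.832	40.1	52
chr1	216781	217366	VRN5_NV_rep2_site_VRN5_NV_0003	240	.	20.622	25.731	24.009	337
chr1	216897	217319	VRN5_NV_rep2_site_VRN5_NV_0005	419	.	15.299	46.878	41.927	35
chr1	217156	217435	VRN5_NV_rep2_site_VRN5_NV_0026	171	.	23.438	19.126	17.126	62
chr1	218311	218698	VRN5_NV_rep2_site_VRN5_NV_0039	54	.	28.904	9.966	5.449	334
chr1	218887	219157	VRN5_NV_rep2_site_VRN5_NV_0018	320	.	21.188	35.774	31.975	36
chr1	223740	224225	VRN5_NV_rep2_site_VRN5_NV_0002	321	.	18.737	32.545	32.149	98
chr1	248005	248468	VRN5_NV_rep2_site_VRN5_NV_0044	393	.	4.292	43.346	39.261	285
chr1	248600	249065	VRN5_NV_rep2_site_VRN5_NV_0001	237	.	4.726	26.515	23.673	69
chr1	251356	251764	VRN5_NV_rep2_site_VRN5_NV_0007	240	.	8.66	25.782	24.004	210
chr1	251413	251692	VRN5_NV_rep2_site_VRN5_NV_0036	282	.	27.152	31.847	28.232	197
chr1	286304	286720	VRN5_NV_rep2_site_VRN5_NV_0045	118	.	10.258	14.37	11.835	244
chr1	294015	294535	VRN5_NV_rep2_site_VRN5_NV_0010	75	.	4.333	9.876	7.51	51
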