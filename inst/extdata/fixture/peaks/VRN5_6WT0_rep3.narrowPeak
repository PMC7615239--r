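chr1	18782	19195	VRN5_6WT0_rep3_site_VRN5_6WT0_0013	404	.	19.808	43.891	40.391	165
chr1	23307	23833	VRN5_6WT0_rep3_site_VRN5_6WT0_0009	23	.	29.976	7.303	2.307	232
chr1	43584	43844	VRN5_6WT0_rep3_site_VRN5_6WT0_0033	205	.	25.349	22.347	20.454	110
chr1	43735	44233	VRN5_6WT0_rep3_site_VRN5_6WT0_0036	100	.	5.668	10.436	9.981	325
chr1	49404	49966	VRN5_6WT0_rep3_site_VRN5_6WT0_0037	446	.	9.356	49.079	44.596	349
chr1	50072	50469	VRN5_6WT0_rep3_site_VRN5_6WT0_0001	334	.	26.299	35.181	33.387	94
chr1	51222	51687	VRN5_6WT0_rep3_site_VRN5_6WT0_0018	378	.	8.218	38.458	37.753	174
chr1	74389	74787	VRN5_6WT0_rep3_site_VRN5_6WT0_0020	28	.	11.324	3.614	2.781	276
chr1	76770	77199	VRN5_6WT0_rep3_site_VRN5_6WT0_0031	149	.	21.199	17.918	14.925	186
chr1	86021	86243	VRN5_6WT0_rep3_site_VRN5_6WT0_0019	45	.	21.621	8.424	4.466	3
chr1	106869	107208	VRN5_6WT0_rep3_site_VRN5_6WT0_0015	253	.	17.785	28.157	25.298	235
chr1	118954	119306	VRN5_6WT0_rep3_site_VRN5_6WT0_0029	150	.	25.297	16.826	14.997	275
chr1	125293	125621	VRN5_6WT0_rep3_site_VRN5_6WT0_0022	127	.	23.614	14.07	12.656	9
chr1	145429	145967	VRN5_6WT0_rep3_site_VRN5_6WT0_0026	444	.	23.38	45.773	44.406	58
chr1	145728	145928	VRN5_6WT0_rep3_site_VRN5_6WT0_0002	98	.	20.479	12.088	9.811	54
chr1	153052	153296	VRN5_6WT0_rep3_site_VRN5_6WT0_0044	20	.	26.89	2.755	2.045	229
chr1	159478	159974	VRN5_6WT0_rep3_site_VRN5_6WT0_0043	95	.	22.073	9.774	9.526	337
chr1	159560	160077	VRN5_6WT0_rep3_site_VRN5_6WT0_0047	201	.	9.907	23.273	20.072	129
chr1	161739	162193	VRN5_6WT0_rep3_site_VRN5_6WT0_0030	66	.	18.818	6.92	6.617	115
chr1	167330	167640	VRN5_6WT0_rep3_site_VRN5_6WT0_0007	164	.	13.946	19.085	16.405	138
chr1	169576	169955	VRN5_6WT0_rep3_site_VRN5_6WT0_0039	278	.	27.875	30.037	27.77	359
chr1	172886	173086	VRN5_6WT0_rep3_site_VRN5_6WT0_0012	36	.	10.752	3.878	3.601	56
chr1	179863	180368	VRN5_6WT0_rep3_site_VRN5_6WT0_0035	482	.	7.841	49.519	48.222	40
chr1	181855	182406	VRN5_6WT0_rep3_site_VRN5_6WT0_0034	434	.	5.094	46.242	43.435	126
chr1	187039	187406	VRN5_6WT0_rep3_site_VRN5_6WT0_0027	468	.	4.25	47.624	46.829	39
chr1	192255	192725	VRN5_6WT0_rep3_site_VRN5_6WT0_0023	338	.	24.378	37.978	33.764	469
chr1	192552	193017	VRN5_6WT0_rep3_site_VRN5_6WT0_0040	122	.	23.183	13.146	12.193	87
chr1	194797	195034	VRN5_6WT0_rep3_site_VRN5_6WT0_0014	222	.	11.172	22.359	22.219	185
chr1	202586	203115	VRN5_6WT0_rep3_site_VRN5_6WT0_0038	398	.	16.998	42.764	39.799	476
chr1	202796	203036	VRN5_6WT0_rep3_site_VRN5_6WT0_0004	216	.	21.89	26.39	21.568	177
chr1	210577	210992	VRN5_6WT0_rep3_site_VRN5_6WT0_0005	78	.	23.83	10.096	7.828	275
chr1	214099	214670	VRN5_6WT0_rep3_site_VRN5_6WT0_0021	34	.	24.035	5.547	3.433	315
chr1	216694	217212	VRN5_6WT0_rep3_site_VRN5_6WT0_0032	79	.	8.726	8.528	7.853	319
chr1	218368	218953	VRN5_6WT0_rep3_site_VRN5_6WT0_0041	35	.	14.036	8.431	3.483	62
chr1	226571	226987	VRN5_6WT0_rep3_site_VRN5_6WT0_0042	459	.	3.968	48.566	45.913	44
chr1	234040	234283	VRN5_6WT0_rep3_site_VRN5_6WT0_0045	296	.	20.531	32.695	29.585	16
chr1	242294	242719	VRN5_6WT0_rep3_site_VRN5_6WT0_0011	328	.	16.986	35.209	32.758	202
chr1	242807	243026	VRN5_6WT0_rep3_site_VRN5_6WT0_0003	469	.	20.92	49.932	46.884	39
chr1	257433	257840	VRN5_6WT0_rep3_site_VRN5_6WT0_0010	24	.	7.727	3.469	2.394	118
chr1	258549	258967	VRN5_6WT0_rep3_site_VRN5_6WT0_0046	402	.	27.399	41.889	40.241	290
chr1	259574	260080	VRN5_6WT0_rep3_site_VRN5_6WT0_0024	404	.	28.652	42.071	40.391	239
chr1	277547	277862	VRN5_6WT0_rep3_site_VRN5_6WT0_0008	41	.	24.365	5.932	4.1	289
chr1	283768	284365	VRN5_6WT0_rep3_site_VRN5_6WT0_0006	444	.	11.426	48.741	44.378	0
chr1	285936	286395	VRN5_6WT0_rep3_site_VRN5_6WT0_0028	261	.	24.048	28.536	26.057	206
chr1	291866	292211	VRN5_6WT0_rep3_site_VRN5_6WT0_0025	490	.	11.482	51.427	48.95	49
chr1	293490	293938	VRN5_6WT0_rep3_site_VRN5_6WT0_0017	455	.	26.257	47.765	45.456	434
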