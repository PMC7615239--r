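chr1	19066	19322	VEL1_6WT0_rep2_site_VEL1_6WT0_0015	344	.	20.386	35.778	34.37	17
chr1	23391	23740	VEL1_6WT0_rep2_site_VEL1_6WT0_0009	332	.	24.331	34.366	33.216	200
chr1	25253	25581	VEL1_6WT0_rep2_site_VEL1_6WT0_0035	73	.	18.199	10.085	7.332	94
chr1	43704	43904	VEL1_6WT0_rep2_site_VEL1_6WT0_0041	446	.	28.072	49.033	44.65	3
chr1	44048	44602	VEL1_6WT0_rep2_site_VEL1_6WT0_0044	64	.	23.125	9.634	6.361	11
chr1	49462	49748	VEL1_6WT0_rep2_site_VEL1_6WT0_0045	370	.	15.412	38.133	37.017	272
chr1	49884	50267	VEL1_6WT0_rep2_site_VEL1_6WT0_0001	183	.	29.735	19.507	18.279	299
chr1	50949	51536	VEL1_6WT0_rep2_site_VEL1_6WT0_0020	281	.	13.402	32.03	28.084	428
chr1	55939	56303	VEL1_6WT0_rep2_site_VEL1_6WT0_0030	392	.	21.555	44.037	39.238	181
chr1	74556	74934	VEL1_6WT0_rep2_site_VEL1_6WT0_0023	488	.	2.465	50.915	48.804	92
chr1	76837	77136	VEL1_6WT0_rep2_site_VEL1_6WT0_0039	78	.	27.603	10.261	7.776	205
chr1	85952	86430	VEL1_6WT0_rep2_site_VEL1_6WT0_0021	75	.	12.763	11.372	7.496	15
chr1	92236	92777	VEL1_6WT0_rep2_site_VEL1_6WT0_0013	211	.	25.218	21.746	21.122	87
chr1	106929	107441	VEL1_6WT0_rep2_site_VEL1_6WT0_0017	158	.	4.493	20.708	15.821	150
chr1	119159	119432	VEL1_6WT0_rep2_site_VEL1_6WT0_0037	336	.	5.114	36.688	33.622	69
chr1	144958	145546	VEL1_6WT0_rep2_site_VEL1_6WT0_0032	341	.	18.769	37.267	34.062	547
chr1	145441	145778	VEL1_6WT0_rep2_site_VEL1_6WT0_0002	167	.	10.47	20.525	16.737	299
chr1	151839	152096	VEL1_6WT0_rep2_site_VEL1_6WT0_0018	59	.	24.94	8.331	5.941	148
chr1	153040	153597	VEL1_6WT0_rep2_site_VEL1_6WT0_0052	318	.	25.148	34.515	31.808	299
chr1	159228	159446	VEL1_6WT0_rep2_site_VEL1_6WT0_0028	65	.	5.157	9.397	6.535	145
chr1	159535	159829	VEL1_6WT0_rep2_site_VEL1_6WT0_0051	132	.	9.365	13.583	13.182	279
chr1	167200	167675	VEL1_6WT0_rep2_site_VEL1_6WT0_0007	90	.	5.797	11.663	8.997	277
chr1	169666	169927	VEL1_6WT0_rep2_site_VEL1_6WT0_0026	338	.	17.751	38.047	33.78	26
chr1	169799	170106	VEL1_6WT0_rep2_site_VEL1_6WT0_0047	67	.	19.823	7.85	6.662	89
chr1	172795	173092	VEL1_6WT0_rep2_site_VEL1_6WT0_0014	442	.	24.883	45.355	44.194	192
chr1	179516	179966	VEL1_6WT0_rep2_site_VEL1_6WT0_0043	86	.	21.271	12.373	8.613	404
chr1	181525	181922	VEL1_6WT0_rep2_site_VEL1_6WT0_0042	253	.	16.917	27.467	25.315	369
chr1	187067	187430	VEL1_6WT0_rep2_site_VEL1_6WT0_0033	289	.	15.335	31.399	28.905	55
chr1	192413	192991	VEL1_6WT0_rep2_site_VEL1_6WT0_0027	223	.	24.51	22.485	22.349	258
chr1	194635	195170	VEL1_6WT0_rep2_site_VEL1_6WT0_0010	229	.	12.412	27.331	22.941	276
chr1	194782	195026	VEL1_6WT0_rep2_site_VEL1_6WT0_0016	69	.	6.091	9.14	6.936	144
chr1	202789	203070	VEL1_6WT0_rep2_site_VEL1_6WT0_0004	112	.	5.691	11.6	11.198	157
chr1	202971	203490	VEL1_6WT0_rep2_site_VEL1_6WT0_0046	48	.	28.909	7.838	4.794	139
chr1	214244	214760	VEL1_6WT0_rep2_site_VEL1_6WT0_0024	40	.	19.083	8.227	3.96	143
chr1	216958	217370	VEL1_6WT0_rep2_site_VEL1_6WT0_0040	391	.	21.922	39.244	39.149	17
chr1	218309	218530	VEL1_6WT0_rep2_site_VEL1_6WT0_0049	367	.	25.818	37.721	36.682	209
chr1	223172	223700	VEL1_6WT0_rep2_site_VEL1_6WT0_0022	218	.	26.459	26.484	21.797	44
chr1	226663	227047	VEL1_6WT0_rep2_site_VEL1_6WT0_0050	33	.	17.519	4.235	3.325	59
chr1	233813	234194	VEL1_6WT0_rep2_site_VEL1_6WT0_0053	383	.	15.071	39.02	38.262	202
chr1	242210	242804	VEL1_6WT0_rep2_site_VEL1_6WT0_0012	286	.	25.074	30.693	28.572	270
chr1	242589	242968	VEL1_6WT0_rep2_site_VEL1_6WT0_0003	489	.	25.837	51.084	48.906	316
chr1	257553	257760	VEL1_6WT0_rep2_site_VEL1_6WT0_0011	88	.	11.603	9.354	8.792	66
chr1	258780	259180	VEL1_6WT0_rep2_site_VEL1_6WT0_0054	80	.	4.991	12.772	8.025	25
chr1	259548	259862	VEL1_6WT0_rep2_site_VEL1_6WT0_0029	98	.	12.082	14.331	9.78	287
chr1	277661	277917	VEL1_6WT0_rep2_site_VEL1_6WT0_0008	108	.	6.728	14.255	10.793	156
chr1	283595	283985	VEL1_6WT0_rep2_site_VEL1_6WT0_0006	365	.	22.908	39.418	36.457	240
chr1	286071	286485	VEL1_6WT0_rep2_site_VEL1_6WT0_0036	163	.	18.61	16.608	16.323	109
chr1	291750	291970	VEL1_6WT0_rep2_site_VEL1_6WT0_0031	357	.	19.106	38.964	35.714	200
chr1	293790	294261	VEL1_6WT0_rep2_site_VEL1_6WT0_0019	141	.	11.963	17.474	14.087	104
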