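chr1	18897	19469	VEL1_6WT0_rep1_site_VEL1_6WT0_0015	321	.	15.023	35.153	32.062	186
chr1	23583	23962	VEL1_6WT0_rep1_site_VEL1_6WT0_0009	296	.	14.7	33.421	29.557	8
chr1	25207	25524	VEL1_6WT0_rep1_site_VEL1_6WT0_0035	50	.	2.534	5.302	5.02	140
chr1	43486	43912	VEL1_6WT0_rep1_site_VEL1_6WT0_0041	129	.	27.109	16.903	12.921	221
chr1	43650	44134	VEL1_6WT0_rep1_site_VEL1_6WT0_0044	420	.	18.654	43.976	42.041	409
chr1	49671	50006	VEL1_6WT0_rep1_site_VEL1_6WT0_0045	273	.	29.4	31.293	27.312	63
chr1	49911	50492	VEL1_6WT0_rep1_site_VEL1_6WT0_0001	84	.	2.869	12.683	8.359	272
chr1	51156	51692	VEL1_6WT0_rep1_site_VEL1_6WT0_0020	102	.	11.713	12.246	10.245	221
chr1	55878	56314	VEL1_6WT0_rep1_site_VEL1_6WT0_0030	323	.	12.243	34.579	32.251	242
chr1	74547	74774	VEL1_6WT0_rep1_site_VEL1_6WT0_0023	135	.	7.182	18.28	13.548	101
chr1	77006	77311	VEL1_6WT0_rep1_site_VEL1_6WT0_0039	78	.	15.54	9.642	7.787	36
chr1	85827	86184	VEL1_6WT0_rep1_site_VEL1_6WT0_0021	49	.	27.457	7.784	4.949	140
chr1	92310	92711	VEL1_6WT0_rep1_site_VEL1_6WT0_0013	364	.	6.555	36.79	36.398	13
chr1	106852	107099	VEL1_6WT0_rep1_site_VEL1_6WT0_0017	135	.	10.922	17.165	13.488	227
chr1	119098	119465	VEL1_6WT0_rep1_site_VEL1_6WT0_0037	84	.	4.296	13.064	8.407	130
chr1	125273	125488	VEL1_6WT0_rep1_site_VEL1_6WT0_0025	240	.	17.506	25.73	23.975	64
chr1	145456	145763	VEL1_6WT0_rep1_site_VEL1_6WT0_0032	394	.	26.689	41.288	39.425	49
chr1	145650	146101	VEL1_6WT0_rep1_site_VEL1_6WT0_0002	69	.	15.843	8.536	6.906	90
chr1	151791	152197	VEL1_6WT0_rep1_site_VEL1_6WT0_0018	443	.	26.622	46.608	44.286	196
chr1	153206	153456	VEL1_6WT0_rep1_site_VEL1_6WT0_0052	232	.	7.049	24.274	23.174	133
chr1	159251	159840	VEL1_6WT0_rep1_site_VEL1_6WT0_0028	305	.	26.936	31.961	30.532	122
chr1	159408	159772	VEL1_6WT0_rep1_site_VEL1_6WT0_0055	129	.	21.191	17.068	12.884	262
chr1	159723	160226	VEL1_6WT0_rep1_site_VEL1_6WT0_0051	52	.	6.051	7.694	5.177	91
chr1	161586	161957	VEL1_6WT0_rep1_site_VEL1_6WT0_0038	319	.	25.62	32.291	31.896	258
chr1	167034	167624	VEL1_6WT0_rep1_site_VEL1_6WT0_0007	122	.	16.993	12.54	12.209	443
chr1	169376	169915	VEL1_6WT0_rep1_site_VEL1_6WT0_0026	399	.	25.522	43.056	39.889	316
chr1	169847	170196	VEL1_6WT0_rep1_site_VEL1_6WT0_0047	406	.	20.807	43.641	40.647	41
chr1	172885	173302	VEL1_6WT0_rep1_site_VEL1_6WT0_0014	175	.	16.358	20.209	17.493	102
chr1	179720	180314	VEL1_6WT0_rep1_site_VEL1_6WT0_0043	351	.	21.133	39.387	35.062	200
chr1	181789	182276	VEL1_6WT0_rep1_site_VEL1_6WT0_0042	324	.	21.358	36.868	32.375	105
chr1	186991	187555	VEL1_6WT0_rep1_site_VEL1_6WT0_0033	212	.	9.117	24.955	21.239	131
chr1	192084	192682	VEL1_6WT0_rep1_site_VEL1_6WT0_0048	300	.	22.721	30.122	29.969	555
chr1	192288	192779	VEL1_6WT0_rep1_site_VEL1_6WT0_0027	72	.	2.642	12.008	7.214	383
chr1	194839	195133	VEL1_6WT0_rep1_site_VEL1_6WT0_0010	76	.	21.682	8.533	7.577	72
chr1	202767	203226	VEL1_6WT0_rep1_site_VEL1_6WT0_0046	401	.	19.079	40.316	40.134	343
chr1	210584	210828	VEL1_6WT0_rep1_site_VEL1_6WT0_0005	276	.	14.578	32.015	27.565	240
chr1	213822	214404	VEL1_6WT0_rep1_site_VEL1_6WT0_0024	362	.	23.269	37.967	36.214	565
chr1	216886	217240	VEL1_6WT0_rep1_site_VEL1_6WT0_0040	308	.	22.112	33.381	30.848	89
chr1	218229	218715	VEL1_6WT0_rep1_site_VEL1_6WT0_0034	201	.	4.865	20.643	20.087	147
chr1	218238	218644	VEL1_6WT0_rep1_site_VEL1_6WT0_0049	440	.	21.772	47.242	43.976	280
chr1	223053	223294	VEL1_6WT0_rep1_site_VEL1_6WT0_0022	247	.	28.478	29.23	24.736	163
chr1	226493	227019	VEL1_6WT0_rep1_site_VEL1_6WT0_0050	153	.	14.692	20.236	15.341	229
chr1	233468	234019	VEL1_6WT0_rep1_site_VEL1_6WT0_0053	39	.	11.308	4.105	3.936	547
chr1	242679	243205	VEL1_6WT0_rep1_site_VEL1_6WT0_0003	460	.	4.022	47.882	45.975	226
chr1	257514	257803	VEL1_6WT0_rep1_site_VEL1_6WT0_0011	179	.	20.136	19.437	17.876	105
chr1	258793	259133	VEL1_6WT0_rep1_site_VEL1_6WT0_0054	220	.	10.687	22.322	22.036	12
chr1	277337	277821	VEL1_6WT0_rep1_site_VEL1_6WT0_0008	42	.	26.301	5.793	4.235	480
chr1	283557	284086	VEL1_6WT0_rep1_site_VEL1_6WT0_0006	278	.	19.163	29.726	27.813	278
chr1	286087	286633	VEL1_6WT0_rep1_site_VEL1_6WT0_0036	48	.	15.459	6.696	4.798	93
chr1	291854	292079	VEL1_6WT0_rep1_site_VEL1_6WT0_0031	83	.	7.328	11.201	8.321	96
chr1	293868	294279	VEL1_6WT0_rep1_site_VEL1_6WT0_0019	150	.	4.36	15.796	15.046	26
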