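chr1	18805	19398	VIN3_NV_rep3_site_VIN3_NV_0031	290	.	2.766	30.71	28.998	306
chr1	19015	19534	VIN3_NV_rep3_site_VIN3_NV_0028	271	.	28.529	27.553	27.111	478
chr1	24696	25121	VIN3_NV_rep3_site_VIN3_NV_0035	492	.	19.656	52.953	49.164	316
chr1	33039	33485	VIN3_NV_rep3_site_VIN3_NV_0033	387	.	25.793	40.767	38.694	326
chr1	33468	33827	VIN3_NV_rep3_site_VIN3_NV_0026	317	.	25.11	33.381	31.698	46
chr1	40012	40246	VIN3_NV_rep3_site_VIN3_NV_0002	294	.	3.382	32.77	29.437	178
chr1	43586	43974	VIN3_NV_rep3_site_VIN3_NV_0021	407	.	19.234	41.559	40.696	41
chr1	43875	44317	VIN3_NV_rep3_site_VIN3_NV_0022	297	.	10.235	29.998	29.724	42
chr1	47811	48327	VIN3_NV_rep3_site_VIN3_NV_0036	148	.	9.444	18.509	14.841	367
chr1	66507	66873	VIN3_NV_rep3_site_VIN3_NV_0042	277	.	27.918	27.79	27.678	203
chr1	76153	76711	VIN3_NV_rep3_site_VIN3_NV_0016	193	.	8.623	22.866	19.334	511
chr1	83274	83794	VIN3_NV_rep3_site_VIN3_NV_0023	311	.	29.867	33.259	31.145	143
chr1	90225	90579	VIN3_NV_rep3_site_VIN3_NV_0029	416	.	25.443	42.788	41.595	101
chr1	91034	91568	VIN3_NV_rep3_site_VIN3_NV_0020	281	.	4.238	28.943	28.078	192
chr1	108925	109274	VIN3_NV_rep3_site_VIN3_NV_0003	444	.	21.411	45.189	44.378	275
chr1	109499	109993	VIN3_NV_rep3_site_VIN3_NV_0018	205	.	20.654	25.001	20.544	416
chr1	119440	119706	VIN3_NV_rep3_site_VIN3_NV_0038	296	.	15.067	29.9	29.645	1
chr1	151465	151909	VIN3_NV_rep3_site_VIN3_NV_0041	285	.	14.19	32.971	28.54	368
chr1	159647	160177	VIN3_NV_rep3_site_VIN3_NV_0043	235	.	8.099	26.292	23.509	60
chr1	169850	170146	VIN3_NV_rep3_site_VIN3_NV_0006	475	.	22.491	48.526	47.528	208
chr1	175604	175963	VIN3_NV_rep3_site_VIN3_NV_0017	254	.	3.647	27.485	25.374	319
chr1	175901	176444	VIN3_NV_rep3_site_VIN3_NV_0011	140	.	29.953	16.335	14.039	300
chr1	184162	184466	VIN3_NV_rep3_site_VIN3_NV_0013	352	.	2.035	38.927	35.237	51
chr1	218681	218925	VIN3_NV_rep3_site_VIN3_NV_0045	143	.	23.226	18.245	14.277	64
chr1	218723	219164	VIN3_NV_rep3_site_VIN3_NV_0027	242	.	26.663	25.326	24.17	157
chr1	241824	242150	VIN3_NV_rep3_site_VIN3_NV_0024	160	.	7.495	19.139	16.018	320
chr1	248569	249040	VIN3_NV_rep3_site_VIN3_NV_0001	385	.	28.404	39.782	38.516	82
chr1	286340	286831	VIN3_NV_rep3_site_VIN3_NV_0051	436	.	11.624	44.99	43.634	123
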