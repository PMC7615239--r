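peak_id	chrom	summit	gene_id	distance	n_candidates	factor	condition
consensus_VIN3_NV_1	chr1	19112	SIMG0002	2	1	VIN3	NV
consensus_VIN3_NV_2	chr1	25013	SIMG0003	147	1	VIN3	NV
consensus_VIN3_NV_3	chr1	33366	SIMG0004	0	1	VIN3	NV
consensus_VIN3_NV_4	chr1	40191	NA	NA	0	VIN3	NV
consensus_VIN3_NV_5	chr1	43628	SIMG0005	0	1	VIN3	NV
consensus_VIN3_NV_6	chr1	48179	NA	NA	0	VIN3	NV
consensus_VIN3_NV_7	chr1	51596	SIMG0006	231	1	VIN3	NV
consensus_VIN3_NV_8	chr1	76665	SIMG0009	0	1	VIN3	NV
consensus_VIN3_NV_9	chr1	83418	SIMG0010	0	1	VIN3	NV
consensus_VIN3_NV_10	chr1	90327	NA	NA	0	VIN3	NV
consensus_VIN3_NV_11	chr1	91227	NA	NA	0	VIN3	NV
consensus_VIN3_NV_12	chr1	102634	SIMG0012	277	1	VIN3	NV
consensus_VIN3_NV_13	chr1	109201	SIMG0013	0	1	VIN3	NV
consensus_VIN3_NV_14	chr1	145590	SIMG0017	0	1	VIN3	NV
consensus_VIN3_NV_15	chr1	151834	SIMG0018	0	1	VIN3	NV
consensus_VIN3_NV_16	chr1	170059	SIMG0020	334	1	VIN3	NV
consensus_VIN3_NV_17	chr1	176202	SIMG0021	0	1	VIN3	NV
consensus_VIN3_NV_18	chr1	184214	SIMG0022	0	1	VIN3	NV
consensus_VIN3_NV_19	chr1	200290	SIMG0024	214	1	VIN3	NV
consensus_VIN3_NV_20	chr1	217233	SIMG0026	0	1	VIN3	NV
consensus_VIN3_NV_21	chr1	218746	SIMG0026	494	1	VIN3	NV
consensus_VIN3_NV_22	chr1	242145	SIMG0029	0	1	VIN3	NV
consensus_VIN3_NV_23	chr1	248652	SIMG0030	0	1	VIN3	NV
consensus_VIN3_NV_24	chr1	251500	SIMG0030	83	1	VIN3	NV
consensus_VIN3_NV_25	chr1	286464	SIMG0034	393	1	VIN3	NV
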