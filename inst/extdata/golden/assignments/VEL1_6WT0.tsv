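peak_id	chrom	summit	gene_id	distance	n_candidates	factor	condition
consensus_VEL1_6WT0_1	chr1	19084	SIMG0002	0	1	VEL1	6WT0
consensus_VEL1_6WT0_2	chr1	23592	NA	NA	0	VEL1	6WT0
consensus_VEL1_6WT0_3	chr1	43708	SIMG0005	22	1	VEL1	6WT0
consensus_VEL1_6WT0_4	chr1	50184	SIMG0006	0	1	VEL1	6WT0
consensus_VEL1_6WT0_5	chr1	51378	SIMG0006	13	1	VEL1	6WT0
consensus_VEL1_6WT0_6	chr1	56121	NA	NA	0	VEL1	6WT0
consensus_VEL1_6WT0_7	chr1	74649	SIMG0009	206	1	VEL1	6WT0
consensus_VEL1_6WT0_8	chr1	92324	SIMG0011	19	1	VEL1	6WT0
consensus_VEL1_6WT0_9	chr1	107080	NA	NA	0	VEL1	6WT0
consensus_VEL1_6WT0_10	chr1	119229	SIMG0014	0	1	VEL1	6WT0
consensus_VEL1_6WT0_11	chr1	125338	SIMG0015	133	1	VEL1	6WT0
consensus_VEL1_6WT0_12	chr1	145741	SIMG0017	36	1	VEL1	6WT0
consensus_VEL1_6WT0_13	chr1	151988	SIMG0018	0	1	VEL1	6WT0
consensus_VEL1_6WT0_14	chr1	153340	SIMG0018	0	1	VEL1	6WT0
consensus_VEL1_6WT0_15	chr1	159374	SIMG0019	79	1	VEL1	6WT0
consensus_VEL1_6WT0_16	chr1	161845	SIMG0019	87	1	VEL1	6WT0
consensus_VEL1_6WT0_17	chr1	167478	SIMG0020	317	1	VEL1	6WT0
consensus_VEL1_6WT0_18	chr1	169889	SIMG0020	164	1	VEL1	6WT0
consensus_VEL1_6WT0_19	chr1	172988	NA	NA	0	VEL1	6WT0
consensus_VEL1_6WT0_20	chr1	179921	NA	NA	0	VEL1	6WT0
consensus_VEL1_6WT0_21	chr1	181895	NA	NA	0	VEL1	6WT0
consensus_VEL1_6WT0_22	chr1	187123	SIMG0022	379	1	VEL1	6WT0
consensus_VEL1_6WT0_23	chr1	192640	SIMG0023	220	1	VEL1	6WT0
consensus_VEL1_6WT0_24	chr1	194927	SIMG0023	448	1	VEL1	6WT0
consensus_VEL1_6WT0_25	chr1	203111	SIMG0024	68	1	VEL1	6WT0
consensus_VEL1_6WT0_26	chr1	210825	SIMG0025	0	1	VEL1	6WT0
consensus_VEL1_6WT0_27	chr1	216976	SIMG0026	19	1	VEL1	6WT0
consensus_VEL1_6WT0_28	chr1	218519	SIMG0026	267	1	VEL1	6WT0
consensus_VEL1_6WT0_29	chr1	223217	NA	NA	0	VEL1	6WT0
consensus_VEL1_6WT0_30	chr1	234016	SIMG0028	63	1	VEL1	6WT0
consensus_VEL1_6WT0_31	chr1	242906	SIMG0029	530	1	VEL1	6WT0
consensus_VEL1_6WT0_32	chr1	283836	SIMG0034	0	1	VEL1	6WT0
consensus_VEL1_6WT0_33	chr1	286181	SIMG0034	110	1	VEL1	6WT0
consensus_VEL1_6WT0_34	chr1	293895	SIMG0035	0	1	VEL1	6WT0
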