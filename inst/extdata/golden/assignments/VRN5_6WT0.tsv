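peak_id	chrom	summit	gene_id	distance	n_candidates	factor	condition
consensus_VRN5_6WT0_1	chr1	18948	SIMG0002	0	1	VRN5	6WT0
consensus_VRN5_6WT0_2	chr1	43695	SIMG0005	9	1	VRN5	6WT0
consensus_VRN5_6WT0_3	chr1	49754	SIMG0006	0	1	VRN5	6WT0
consensus_VRN5_6WT0_4	chr1	51397	SIMG0006	32	1	VRN5	6WT0
consensus_VRN5_6WT0_5	chr1	74666	SIMG0009	189	1	VRN5	6WT0
consensus_VRN5_6WT0_6	chr1	76957	SIMG0009	0	1	VRN5	6WT0
consensus_VRN5_6WT0_7	chr1	107105	NA	NA	0	VRN5	6WT0
consensus_VRN5_6WT0_8	chr1	119230	SIMG0014	0	1	VRN5	6WT0
consensus_VRN5_6WT0_9	chr1	125303	SIMG0015	168	1	VRN5	6WT0
consensus_VRN5_6WT0_10	chr1	145488	SIMG0017	0	1	VRN5	6WT0
consensus_VRN5_6WT0_11	chr1	159816	SIMG0019	0	1	VRN5	6WT0
consensus_VRN5_6WT0_12	chr1	167469	SIMG0020	326	1	VRN5	6WT0
consensus_VRN5_6WT0_13	chr1	169936	SIMG0020	211	1	VRN5	6WT0
consensus_VRN5_6WT0_14	chr1	179904	NA	NA	0	VRN5	6WT0
consensus_VRN5_6WT0_15	chr1	181982	NA	NA	0	VRN5	6WT0
consensus_VRN5_6WT0_16	chr1	187079	SIMG0022	335	1	VRN5	6WT0
consensus_VRN5_6WT0_17	chr1	192725	SIMG0023	135	1	VRN5	6WT0
consensus_VRN5_6WT0_18	chr1	194983	SIMG0023	504	1	VRN5	6WT0
consensus_VRN5_6WT0_19	chr1	203063	SIMG0024	20	1	VRN5	6WT0
consensus_VRN5_6WT0_20	chr1	218431	SIMG0026	179	1	VRN5	6WT0
consensus_VRN5_6WT0_21	chr1	234057	SIMG0028	104	1	VRN5	6WT0
consensus_VRN5_6WT0_22	chr1	242497	SIMG0029	121	1	VRN5	6WT0
consensus_VRN5_6WT0_23	chr1	258840	SIMG0031	64	1	VRN5	6WT0
consensus_VRN5_6WT0_24	chr1	259814	NA	NA	0	VRN5	6WT0
consensus_VRN5_6WT0_25	chr1	283769	SIMG0034	0	1	VRN5	6WT0
consensus_VRN5_6WT0_26	chr1	291916	SIMG0035	201	1	VRN5	6WT0
consensus_VRN5_6WT0_27	chr1	293925	SIMG0035	0	1	VRN5	6WT0
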