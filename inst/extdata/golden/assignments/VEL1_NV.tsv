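peak_id	chrom	summit	gene_id	distance	n_candidates	factor	condition
consensus_VEL1_NV_1	chr1	19203	SIMG0002	93	1	VEL1	NV
consensus_VEL1_NV_2	chr1	24993	SIMG0003	167	1	VEL1	NV
consensus_VEL1_NV_3	chr1	33516	SIMG0004	0	1	VEL1	NV
consensus_VEL1_NV_4	chr1	38470	NA	NA	0	VEL1	NV
consensus_VEL1_NV_5	chr1	40158	NA	NA	0	VEL1	NV
consensus_VEL1_NV_6	chr1	43333	SIMG0005	0	1	VEL1	NV
consensus_VEL1_NV_7	chr1	48199	NA	NA	0	VEL1	NV
consensus_VEL1_NV_8	chr1	51602	SIMG0006	237	1	VEL1	NV
consensus_VEL1_NV_9	chr1	66751	SIMG0008	0	1	VEL1	NV
consensus_VEL1_NV_10	chr1	83399	SIMG0010	0	1	VEL1	NV
consensus_VEL1_NV_11	chr1	90304	NA	NA	0	VEL1	NV
consensus_VEL1_NV_12	chr1	102606	SIMG0012	249	1	VEL1	NV
consensus_VEL1_NV_13	chr1	109292	SIMG0013	0	1	VEL1	NV
consensus_VEL1_NV_14	chr1	119422	SIMG0014	0	1	VEL1	NV
consensus_VEL1_NV_15	chr1	125360	SIMG0015	111	1	VEL1	NV
consensus_VEL1_NV_16	chr1	135183	SIMG0016	0	1	VEL1	NV
consensus_VEL1_NV_17	chr1	145616	SIMG0017	0	1	VEL1	NV
consensus_VEL1_NV_18	chr1	159657	SIMG0019	0	1	VEL1	NV
consensus_VEL1_NV_19	chr1	165916	NA	NA	0	VEL1	NV
consensus_VEL1_NV_20	chr1	170072	SIMG0020	347	1	VEL1	NV
consensus_VEL1_NV_21	chr1	176135	SIMG0021	0	1	VEL1	NV
consensus_VEL1_NV_22	chr1	184254	SIMG0022	0	1	VEL1	NV
consensus_VEL1_NV_23	chr1	200225	SIMG0024	279	1	VEL1	NV
consensus_VEL1_NV_24	chr1	217103	SIMG0026	0	1	VEL1	NV
consensus_VEL1_NV_25	chr1	218636	SIMG0026	384	1	VEL1	NV
consensus_VEL1_NV_26	chr1	224109	SIMG0027	121	1	VEL1	NV
consensus_VEL1_NV_27	chr1	238416	NA	NA	0	VEL1	NV
consensus_VEL1_NV_28	chr1	242161	SIMG0029	0	1	VEL1	NV
consensus_VEL1_NV_29	chr1	248670	SIMG0030	0	1	VEL1	NV
consensus_VEL1_NV_30	chr1	251552	SIMG0030	135	1	VEL1	NV
consensus_VEL1_NV_31	chr1	286491	SIMG0034	420	1	VEL1	NV
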