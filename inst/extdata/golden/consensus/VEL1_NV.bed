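chr1	18718	19714	consensus_VEL1_NV_1	0	.	3
chr1	24522	25489	consensus_VEL1_NV_2	0	.	3
chr1	33243	33807	consensus_VEL1_NV_3	0	.	3
chr1	38217	38807	consensus_VEL1_NV_4	0	.	2
chr1	39880	40350	consensus_VEL1_NV_5	0	.	2
chr1	43264	44111	consensus_VEL1_NV_6	0	.	3
chr1	47991	48351	consensus_VEL1_NV_7	0	.	2
chr1	51367	51924	consensus_VEL1_NV_8	0	.	2
chr1	66591	67115	consensus_VEL1_NV_9	0	.	3
chr1	83136	83720	consensus_VEL1_NV_10	0	.	2
chr1	90124	90830	consensus_VEL1_NV_11	0	.	2
chr1	101954	102931	consensus_VEL1_NV_12	0	.	3
chr1	109168	109950	consensus_VEL1_NV_13	0	.	2
chr1	119179	119785	consensus_VEL1_NV_14	0	.	3
chr1	125042	125684	consensus_VEL1_NV_15	0	.	3
chr1	134753	135700	consensus_VEL1_NV_16	0	.	2
chr1	145161	145774	consensus_VEL1_NV_17	0	.	2
chr1	159168	159768	consensus_VEL1_NV_18	0	.	2
chr1	165783	166138	consensus_VEL1_NV_19	0	.	2
chr1	169767	170270	consensus_VEL1_NV_20	0	.	2
chr1	175677	176393	consensus_VEL1_NV_21	0	.	3
chr1	184121	184729	consensus_VEL1_NV_22	0	.	2
chr1	200069	200911	consensus_VEL1_NV_23	0	.	3
chr1	216698	217745	consensus_VEL1_NV_24	0	.	3
chr1	218470	219281	consensus_VEL1_NV_25	0	.	3
chr1	223768	224272	consensus_VEL1_NV_26	0	.	3
chr1	238090	238701	consensus_VEL1_NV_27	0	.	2
chr1	241801	242396	consensus_VEL1_NV_28	0	.	3
chr1	248134	248983	consensus_VEL1_NV_29	0	.	3
chr1	250983	251834	consensus_VEL1_NV_30	0	.	2
chr1	286278	286837	consensus_VEL1_NV_31	0	.	2
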