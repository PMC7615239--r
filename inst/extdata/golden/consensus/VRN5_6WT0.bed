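chr1	18471	19239	consensus_VRN5_6WT0_1	0	.	3
chr1	43517	44064	consensus_VRN5_6WT0_2	0	.	3
chr1	49404	49966	consensus_VRN5_6WT0_3	0	.	2
chr1	51196	51758	consensus_VRN5_6WT0_4	0	.	3
chr1	74510	75093	consensus_VRN5_6WT0_5	0	.	2
chr1	76409	77199	consensus_VRN5_6WT0_6	0	.	3
chr1	106863	107208	consensus_VRN5_6WT0_7	0	.	2
chr1	118954	119306	consensus_VRN5_6WT0_8	0	.	2
chr1	125115	125621	consensus_VRN5_6WT0_9	0	.	3
chr1	145429	146046	consensus_VRN5_6WT0_10	0	.	2
chr1	159433	160077	consensus_VRN5_6WT0_11	0	.	3
chr1	167067	167640	consensus_VRN5_6WT0_12	0	.	2
chr1	169576	170138	consensus_VRN5_6WT0_13	0	.	2
chr1	179760	180474	consensus_VRN5_6WT0_14	0	.	3
chr1	181831	182406	consensus_VRN5_6WT0_15	0	.	2
chr1	186939	187406	consensus_VRN5_6WT0_16	0	.	3
chr1	192255	193017	consensus_VRN5_6WT0_17	0	.	3
chr1	194797	195216	consensus_VRN5_6WT0_18	0	.	2
chr1	202586	203415	consensus_VRN5_6WT0_19	0	.	3
chr1	218207	218696	consensus_VRN5_6WT0_20	0	.	2
chr1	233749	234283	consensus_VRN5_6WT0_21	0	.	3
chr1	242124	243026	consensus_VRN5_6WT0_22	0	.	3
chr1	258549	259035	consensus_VRN5_6WT0_23	0	.	2
chr1	259466	260080	consensus_VRN5_6WT0_24	0	.	3
chr1	283530	284365	consensus_VRN5_6WT0_25	0	.	2
chr1	291616	292211	consensus_VRN5_6WT0_26	0	.	3
chr1	293490	294175	consensus_VRN5_6WT0_27	0	.	2
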