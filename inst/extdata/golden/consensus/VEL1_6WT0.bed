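chr1	18887	19470	consensus_VEL1_6WT0_1	0	.	3
chr1	23391	23962	consensus_VEL1_6WT0_2	0	.	2
chr1	43217	44395	consensus_VEL1_6WT0_3	0	.	3
chr1	49448	50350	consensus_VEL1_6WT0_4	0	.	3
chr1	50944	51692	consensus_VEL1_6WT0_5	0	.	3
chr1	55769	56314	consensus_VEL1_6WT0_6	0	.	3
chr1	74312	74934	consensus_VEL1_6WT0_7	0	.	3
chr1	92040	92777	consensus_VEL1_6WT0_8	0	.	3
chr1	106852	107441	consensus_VEL1_6WT0_9	0	.	2
chr1	118772	119432	consensus_VEL1_6WT0_10	0	.	2
chr1	125273	125631	consensus_VEL1_6WT0_11	0	.	2
chr1	144958	145778	consensus_VEL1_6WT0_12	0	.	3
chr1	151501	152197	consensus_VEL1_6WT0_13	0	.	2
chr1	153040	153660	consensus_VEL1_6WT0_14	0	.	3
chr1	159209	159999	consensus_VEL1_6WT0_15	0	.	3
chr1	161586	162049	consensus_VEL1_6WT0_16	0	.	2
chr1	167034	167852	consensus_VEL1_6WT0_17	0	.	2
chr1	169376	170196	consensus_VEL1_6WT0_18	0	.	2
chr1	172795	173302	consensus_VEL1_6WT0_19	0	.	2
chr1	179720	180413	consensus_VEL1_6WT0_20	0	.	2
chr1	181525	182276	consensus_VEL1_6WT0_21	0	.	2
chr1	186863	187555	consensus_VEL1_6WT0_22	0	.	3
chr1	192084	192991	consensus_VEL1_6WT0_23	0	.	3
chr1	194623	195170	consensus_VEL1_6WT0_24	0	.	2
chr1	202767	203469	consensus_VEL1_6WT0_25	0	.	3
chr1	210584	211217	consensus_VEL1_6WT0_26	0	.	2
chr1	216770	217370	consensus_VEL1_6WT0_27	0	.	3
chr1	218229	218758	consensus_VEL1_6WT0_28	0	.	3
chr1	222964	223700	consensus_VEL1_6WT0_29	0	.	3
chr1	233797	234194	consensus_VEL1_6WT0_30	0	.	2
chr1	242209	243205	consensus_VEL1_6WT0_31	0	.	3
chr1	283557	284086	consensus_VEL1_6WT0_32	0	.	3
chr1	285984	286529	consensus_VEL1_6WT0_33	0	.	2
chr1	293790	294279	consensus_VEL1_6WT0_34	0	.	3
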