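chr1	18751	19256	consensus_VIN3_6WT0_1	0	.	3
chr1	23563	24121	consensus_VIN3_6WT0_2	0	.	3
chr1	43356	44403	consensus_VIN3_6WT0_3	0	.	3
chr1	49621	50587	consensus_VIN3_6WT0_4	0	.	2
chr1	51120	51922	consensus_VIN3_6WT0_5	0	.	2
chr1	74487	74977	consensus_VIN3_6WT0_6	0	.	2
chr1	76792	77309	consensus_VIN3_6WT0_7	0	.	2
chr1	85622	86245	consensus_VIN3_6WT0_8	0	.	3
chr1	91940	92366	consensus_VIN3_6WT0_9	0	.	2
chr1	118966	119240	consensus_VIN3_6WT0_10	0	.	2
chr1	153139	153509	consensus_VIN3_6WT0_11	0	.	2
chr1	159284	159884	consensus_VIN3_6WT0_12	0	.	2
chr1	161499	162094	consensus_VIN3_6WT0_13	0	.	3
chr1	169507	170043	consensus_VIN3_6WT0_14	0	.	2
chr1	179488	180141	consensus_VIN3_6WT0_15	0	.	2
chr1	181458	182057	consensus_VIN3_6WT0_16	0	.	3
chr1	194664	195087	consensus_VIN3_6WT0_17	0	.	2
chr1	202828	203494	consensus_VIN3_6WT0_18	0	.	2
chr1	210602	211148	consensus_VIN3_6WT0_19	0	.	2
chr1	214025	214748	consensus_VIN3_6WT0_20	0	.	2
chr1	216627	217333	consensus_VIN3_6WT0_21	0	.	3
chr1	218248	218863	consensus_VIN3_6WT0_22	0	.	3
chr1	233805	234415	consensus_VIN3_6WT0_23	0	.	2
chr1	242279	243192	consensus_VIN3_6WT0_24	0	.	3
chr1	258457	259256	consensus_VIN3_6WT0_25	0	.	3
chr1	259564	259855	consensus_VIN3_6WT0_26	0	.	2
chr1	285986	286342	consensus_VIN3_6WT0_27	0	.	2
chr1	291866	292355	consensus_VIN3_6WT0_28	0	.	2
chr1	293778	294203	consensus_VIN3_6WT0_29	0	.	2
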