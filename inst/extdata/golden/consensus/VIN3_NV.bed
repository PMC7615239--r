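chr1	18805	19806	consensus_VIN3_NV_1	0	.	3
chr1	24426	25121	consensus_VIN3_NV_2	0	.	3
chr1	33039	33827	consensus_VIN3_NV_3	0	.	3
chr1	40012	40670	consensus_VIN3_NV_4	0	.	2
chr1	43351	44317	consensus_VIN3_NV_5	0	.	3
chr1	47811	48380	consensus_VIN3_NV_6	0	.	2
chr1	51288	51616	consensus_VIN3_NV_7	0	.	2
chr1	76153	77131	consensus_VIN3_NV_8	0	.	2
chr1	83274	83794	consensus_VIN3_NV_9	0	.	2
chr1	90174	90696	consensus_VIN3_NV_10	0	.	2
chr1	90700	91568	consensus_VIN3_NV_11	0	.	3
chr1	102249	102768	consensus_VIN3_NV_12	0	.	2
chr1	108925	110229	consensus_VIN3_NV_13	0	.	2
chr1	145430	146309	consensus_VIN3_NV_14	0	.	2
chr1	151465	152014	consensus_VIN3_NV_15	0	.	2
chr1	169770	170146	consensus_VIN3_NV_16	0	.	2
chr1	175604	176444	consensus_VIN3_NV_17	0	.	3
chr1	184034	184522	consensus_VIN3_NV_18	0	.	3
chr1	199794	200771	consensus_VIN3_NV_19	0	.	2
chr1	216482	217590	consensus_VIN3_NV_20	0	.	2
chr1	218631	219395	consensus_VIN3_NV_21	0	.	3
chr1	241824	242315	consensus_VIN3_NV_22	0	.	2
chr1	248507	249040	consensus_VIN3_NV_23	0	.	2
chr1	251205	251798	consensus_VIN3_NV_24	0	.	2
chr1	286116	286831	consensus_VIN3_NV_25	0	.	3
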