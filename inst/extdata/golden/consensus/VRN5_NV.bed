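chr1	19057	20011	consensus_VRN5_NV_1	0	.	3
chr1	24622	25483	consensus_VRN5_NV_2	0	.	3
chr1	33323	33872	consensus_VRN5_NV_3	0	.	2
chr1	43424	43999	consensus_VRN5_NV_4	0	.	2
chr1	44595	45469	consensus_VRN5_NV_5	0	.	2
chr1	47935	48651	consensus_VRN5_NV_6	0	.	3
chr1	76419	76845	consensus_VRN5_NV_7	0	.	3
chr1	83193	83548	consensus_VRN5_NV_8	0	.	2
chr1	90051	90603	consensus_VRN5_NV_9	0	.	2
chr1	102098	102698	consensus_VRN5_NV_10	0	.	2
chr1	125001	125490	consensus_VRN5_NV_11	0	.	3
chr1	134660	135531	consensus_VRN5_NV_12	0	.	3
chr1	145206	145773	consensus_VRN5_NV_13	0	.	2
chr1	165871	166496	consensus_VRN5_NV_14	0	.	2
chr1	175895	176639	consensus_VRN5_NV_15	0	.	2
chr1	183864	184400	consensus_VRN5_NV_16	0	.	2
chr1	210303	210976	consensus_VRN5_NV_17	0	.	2
chr1	216750	217523	consensus_VRN5_NV_18	0	.	3
chr1	218528	219157	consensus_VRN5_NV_19	0	.	2
chr1	251316	251899	consensus_VRN5_NV_20	0	.	3
chr1	286304	286874	consensus_VRN5_NV_21	0	.	2
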