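peak_id	chrom	summit	gene_id	distance	n_candidates	factor	condition
consensus_VRN5_NV_1	chr1	19508	SIMG0002	398	1	VRN5	NV
consensus_VRN5_NV_2	chr1	24975	SIMG0003	185	1	VRN5	NV
consensus_VRN5_NV_3	chr1	33577	SIMG0004	0	1	VRN5	NV
consensus_VRN5_NV_4	chr1	43807	SIMG0005	121	1	VRN5	NV
consensus_VRN5_NV_5	chr1	45077	NA	NA	0	VRN5	NV
consensus_VRN5_NV_6	chr1	48144	NA	NA	0	VRN5	NV
consensus_VRN5_NV_7	chr1	76710	SIMG0009	0	1	VRN5	NV
consensus_VRN5_NV_8	chr1	83419	SIMG0010	0	1	VRN5	NV
consensus_VRN5_NV_9	chr1	90327	NA	NA	0	VRN5	NV
consensus_VRN5_NV_10	chr1	102377	SIMG0012	20	1	VRN5	NV
consensus_VRN5_NV_11	chr1	125307	SIMG0015	164	1	VRN5	NV
consensus_VRN5_NV_12	chr1	135131	SIMG0016	0	1	VRN5	NV
consensus_VRN5_NV_13	chr1	145526	SIMG0017	0	1	VRN5	NV
consensus_VRN5_NV_14	chr1	166001	NA	NA	0	VRN5	NV
consensus_VRN5_NV_15	chr1	176180	SIMG0021	0	1	VRN5	NV
consensus_VRN5_NV_16	chr1	184213	SIMG0022	0	1	VRN5	NV
consensus_VRN5_NV_17	chr1	210757	SIMG0025	0	1	VRN5	NV
consensus_VRN5_NV_18	chr1	217065	SIMG0026	0	1	VRN5	NV
consensus_VRN5_NV_19	chr1	218646	SIMG0026	394	1	VRN5	NV
consensus_VRN5_NV_20	chr1	251611	SIMG0030	194	1	VRN5	NV
consensus_VRN5_NV_21	chr1	286549	SIMG0034	478	1	VRN5	NV
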