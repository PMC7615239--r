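peak_id	chrom	summit	gene_id	distance	n_candidates	factor	condition
consensus_VIN3_6WT0_1	chr1	19068	SIMG0002	0	1	VIN3	6WT0
consensus_VIN3_6WT0_2	chr1	23600	NA	NA	0	VIN3	6WT0
consensus_VIN3_6WT0_3	chr1	44061	SIMG0005	375	1	VIN3	6WT0
consensus_VIN3_6WT0_4	chr1	50158	SIMG0006	0	1	VIN3	6WT0
consensus_VIN3_6WT0_5	chr1	51363	SIMG0006	0	1	VIN3	6WT0
consensus_VIN3_6WT0_6	chr1	74680	SIMG0009	175	1	VIN3	6WT0
consensus_VIN3_6WT0_7	chr1	77059	SIMG0009	0	1	VIN3	6WT0
consensus_VIN3_6WT0_8	chr1	85971	SIMG0010	0	1	VIN3	6WT0
consensus_VIN3_6WT0_9	chr1	92210	SIMG0011	133	1	VIN3	6WT0
consensus_VIN3_6WT0_10	chr1	119205	SIMG0014	0	1	VIN3	6WT0
consensus_VIN3_6WT0_11	chr1	153356	SIMG0018	4	1	VIN3	6WT0
consensus_VIN3_6WT0_12	chr1	159400	SIMG0019	53	1	VIN3	6WT0
consensus_VIN3_6WT0_13	chr1	161798	SIMG0019	40	1	VIN3	6WT0
consensus_VIN3_6WT0_14	chr1	169932	SIMG0020	207	1	VIN3	6WT0
consensus_VIN3_6WT0_15	chr1	179943	NA	NA	0	VIN3	6WT0
consensus_VIN3_6WT0_16	chr1	181809	NA	NA	0	VIN3	6WT0
consensus_VIN3_6WT0_17	chr1	194930	SIMG0023	451	1	VIN3	6WT0
consensus_VIN3_6WT0_18	chr1	203154	SIMG0024	111	1	VIN3	6WT0
consensus_VIN3_6WT0_19	chr1	210806	SIMG0025	0	1	VIN3	6WT0
consensus_VIN3_6WT0_20	chr1	214463	NA	NA	0	VIN3	6WT0
consensus_VIN3_6WT0_21	chr1	216921	SIMG0026	74	1	VIN3	6WT0
consensus_VIN3_6WT0_22	chr1	218574	SIMG0026	322	1	VIN3	6WT0
consensus_VIN3_6WT0_23	chr1	233974	SIMG0028	21	1	VIN3	6WT0
consensus_VIN3_6WT0_24	chr1	242434	SIMG0029	58	1	VIN3	6WT0
consensus_VIN3_6WT0_25	chr1	258798	SIMG0031	22	1	VIN3	6WT0
consensus_VIN3_6WT0_26	chr1	259812	NA	NA	0	VIN3	6WT0
consensus_VIN3_6WT0_27	chr1	286234	SIMG0034	163	1	VIN3	6WT0
consensus_VIN3_6WT0_28	chr1	292052	SIMG0035	65	1	VIN3	6WT0
consensus_VIN3_6WT0_29	chr1	293883	SIMG0035	0	1	VIN3	6WT0
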