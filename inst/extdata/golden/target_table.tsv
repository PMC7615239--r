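factor	condition	n_peaks	n_genes
VEL1	6WT0	34	20
VEL1	NV	31	23
VIN3	6WT0	29	19
VIN3	NV	25	19
VRN5	6WT0	27	18
VRN5	NV	21	16
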