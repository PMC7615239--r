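set	VEL1	VIN3	VRN5
VEL1	100	71	58.1
VIN3	92	100	64
VRN5	85.7	76.2	100
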