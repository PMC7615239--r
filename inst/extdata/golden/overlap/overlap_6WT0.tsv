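set	VEL1	VIN3	VRN5
VEL1	100	67.6	67.6
VIN3	79.3	100	69
VRN5	85.2	74.1	100
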