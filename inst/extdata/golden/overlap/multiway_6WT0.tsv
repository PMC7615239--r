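VIN3	VRN5	combination	count
FALSE	FALSE	none	4
FALSE	TRUE	VRN5	7
TRUE	FALSE	VIN3	7
TRUE	TRUE	VIN3+VRN5	16
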