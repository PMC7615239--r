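genome: genome.tsv
annotation: genes.gff3
peaks:
- factor: VEL1
  condition: 6WT0
  replicate: rep1
  path: peaks/VEL1_6WT0_rep1.narrowPeak
- factor: VEL1
  condition: 6WT0
  replicate: rep2
  path: peaks/VEL1_6WT0_rep2.narrowPeak
- factor: VEL1
  condition: 6WT0
  replicate: rep3
  path: peaks/VEL1_6WT0_rep3.narrowPeak
- factor: VEL1
  condition: NV
  replicate: rep1
  path: peaks/VEL1_NV_rep1.narrowPeak
- factor: VEL1
  condition: NV
  replicate: rep2
  path: peaks/VEL1_NV_rep2.narrowPeak
- factor: VEL1
  condition: NV
  replicate: rep3
  path: peaks/VEL1_NV_rep3.narrowPeak
- factor: VIN3
  condition: 6WT0
  replicate: rep1
  path: peaks/VIN3_6WT0_rep1.narrowPeak
- factor: VIN3
  condition: 6WT0
  replicate: rep2
  path: peaks/VIN3_6WT0_rep2.narrowPeak
- factor: VIN3
  condition: 6WT0
  replicate: rep3
  path: peaks/VIN3_6WT0_rep3.narrowPeak
- factor: VIN3
  condition: NV
  replicate: rep1
  path: peaks/VIN3_NV_rep1.narrowPeak
- factor: VIN3
  condition: NV
  replicate: rep2
  path: peaks/VIN3_NV_rep2.narrowPeak
- factor: VIN3
  condition: NV
  replicate: rep3
  path: peaks/VIN3_NV_rep3.narrowPeak
- factor: VRN5
  condition: 6WT0
  replicate: rep1
  path: peaks/VRN5_6WT0_rep1.narrowPeak
- factor: VRN5
  condition: 6WT0
  replicate: rep2
  path: peaks/VRN5_6WT0_rep2.narrowPeak
- factor: VRN5
  condition: 6WT0
  replicate: rep3
  path: peaks/VRN5_6WT0_rep3.narrowPeak
- factor: VRN5
  condition: NV
  replicate: rep1
  path: peaks/VRN5_NV_rep1.narrowPeak
- factor: VRN5
  condition: NV
  replicate: rep2
  path: peaks/VRN5_NV_rep2.narrowPeak
- factor: VRN5
  condition: NV
  replicate: rep3
  path: peaks/VRN5_NV_rep3.narrowPeak

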