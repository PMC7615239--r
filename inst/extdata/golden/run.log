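stage load: reading genome, annotation and peak files
stage filter: retaining peaks with -log10(Q) >= 10
stage consensus: min_support = 2
stage assign: summit-based gene assignment
stage table: target-gene counts
stage overlap: co-occupancy matrices per condition
stage metagene: no coverage files configured; stage skipped
run complete
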