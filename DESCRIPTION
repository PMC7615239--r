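Package: chipsummit
Title: Consensus Peaks, Summit-Based Gene Assignment, Co-Occupancy and
    Metagene Profiles for ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of ChIP-seq peak calls: significance
    filtering of narrowPeak records, replicate-consensus peak construction,
    summit-based assignment of peaks to genes within a fixed window around
    the transcription unit, pairwise and multi-way co-occupancy statistics
    between factors, gene-set comparisons against external target lists,
    and RPGC-normalized (1x genomic content) metagene coverage profiles
    over scaled gene bodies with fixed flanks. Includes a deterministic
    simulator of genomes, gene annotations, replicate peak sets with
    controlled reproducibility and inter-factor sharing, and coverage
    tracks, so that every stage of the pipeline can be validated against
    planted truth. A config-driven pipeline runner and a thin command-line
    wrapper orchestrate the stages with deterministic outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
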