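Package: cprnaseq
Title: End-Chemistry-Aware Simulation and Analysis of cP-RNA and piRNA
    Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the RNA 3'/5' end chemistry (2',3'-cyclic phosphate,
    monophosphate, hydroxyl, 2'-O-methyl) that determines which molecules
    each small-RNA sequencing protocol (piRNA-seq, cP-RNA-seq, P-cP-RNA-seq,
    OH-RNA-seq) can capture; simulates dinucleotide-preferential
    endonucleolytic cleavage and piRNA maturation with full ground-truth
    lineage; and implements the downstream statistics used to relate
    cyclic-phosphate RNAs to piRNAs: hierarchical read mapping with mismatch
    tolerance, tRNA-half classification, cleavage-flank nucleotide
    composition, cross-library mapping ratios, terminal-position match
    profiles, RPM correlation, ping-pong signal, and spike-in normalized
    fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
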