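Package: dsbscan
Title: CRISPR-Cas Off-Target Discovery from MRE11 ChIP-Seq-Style Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery of CRISPR-Cas cleavage sites from paired-end
    ChIP-seq-style alignments of the DNA repair factor MRE11. Implements read
    filtering and equal-depth subsetting, fragment-midpoint candidate detection
    with a minimum-support cutoff, protospacer/PAM mismatch matching, no-nuclease
    control subtraction, reads-per-million (RPM) enrichment in fixed windows
    around cut sites with offset background quantification, flank-anchored
    amplicon indel calling, and rank-based paired/unpaired comparison statistics.
    Includes a synthetic-data generator that plants on- and off-target
    protospacers in a toy genome and emulates MRE11 fragment accumulation at cut
    sites, with and without DNA-PKcs inhibition, so the whole workflow is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
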