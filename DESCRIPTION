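Package: pepdisplay
Title: Bacterial Peptide Display Screens for Kinase Specificity Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design, simulation and analysis of bacterial peptide display
    deep-sequencing screens used to profile tyrosine kinase substrate
    specificity. Builds the genetically encoded library oligo pools (defined
    phosphosite, NNS degenerate X5-Y-X5, and scanning mutagenesis
    architectures), processes paired-end amplicon reads (merge, flank-anchored
    insert extraction, translation with amber-codon annotation), aggregates
    counts, and computes enrichment scores for discrete peptides,
    position-specific residue matrices with central-column masking, and
    wild-type-normalized scanning mutagenesis matrices, including the
    one-amber filtering mode used with genetic code expansion. A built-in
    screen simulator with a known position-weight specificity model generates
    sorted/unsorted FASTQ sample pairs for end-to-end validation, and a
    planner implements the protocol's molarity, dilution, sequencing-depth and
    loading-mix arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
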