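Package: fibermir
Title: MicroRNA Discovery and Expression Profiling from Small RNA
    Sequencing of Elongating Cotton Fibers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for plant microRNA analysis from small RNA
    deep sequencing, modelled on developmental time-course libraries from
    elongating cotton (Gossypium) fibers.  Covers adaptor trimming and read
    collapsing, contaminant (rRNA/tRNA/snRNA/snoRNA/repeat) annotation,
    exact genome mapping, known-miRNA assignment with mismatch tolerance,
    novel-miRNA prediction from hairpin structure criteria (minimum folding
    free energy, MFEI, duplex mismatches, asymmetric bulges, read
    dominance), reads-per-ten-million normalization with complete-linkage
    expression clustering into temporal classes, position-weighted
    miRNA-target complementarity scoring, 5'-RACE cleavage-site mapping,
    and 2^-ddCt relative quantification.  A seeded synthetic-data generator
    produces every input with known ground truth so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rcpp,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: ViennaRNA RNAfold (optional thermodynamic folding
    backend; a built-in base-pair-maximization folder is used otherwise)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
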