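Package: landingpad
Title: Two-Step CRISPR/Cas Genome-Editing Design with Engineered
    Landing-Pad Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design engine for two-step CRISPR/Cas genome editing. Given a
    genome, an annotated feature, and an RNA-guided nuclease (RGN) target
    motif described in an IUPAC grammar, the package enumerates and ranks
    candidate cut sites, expands feature bounds until a quality-controlled
    target is available, generates a genome-unique engineered landing-pad
    target, assembles step-1 (knock-out) and step-2 (add-back) donor DNAs,
    simulates homology-directed repair through the wild-type (+),
    intermediate (deletion) and add-back genome states, and selects an
    annealing-optimized set of validation PCR primers with in-silico PCR
    predictions for colony-PCR genotyping. Guide quality control includes
    polyT and GC filters, a Hsu-Zhang aggregate off-target specificity
    score, an optional CFD table scorer, and a pluggable on-target scorer
    seam. A seeded synthetic-genome generator makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
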