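Package: sorfscan
Title: Discovery of Short FAST-Like Fusogen ORFs in LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A discovery pipeline for short, FAST-protein-like candidate
    fusogens (sORF2-type) encoded by LTR retrotransposons and non-enveloped
    viruses. Enumerates all ATG-initiated open reading frames in nucleotide
    sequences, profiles each translated ORF for the hallmark features of
    single-pass membrane fusogens (transmembrane segment by sliding-window
    hydropathy, N-terminal glycine myristoylation motif, juxtamembrane
    polybasic patch, amphipathic helical moments, aromatic-belt tyrosine),
    applies a configurable composite filter, builds profile hidden Markov
    models from multiple sequence alignments and scans protein databases
    with Viterbi/forward scoring under an empirical shuffle null, scans
    annotated genomes at the level of transposon insertions, and tests
    enrichment of transposon groups in designated 100-kb genomic tiles by
    permutation. Includes seeded synthetic-data generators (planted
    positives, feature-ablated decoys, toy genomes, tile fixtures) so every
    stage is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
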