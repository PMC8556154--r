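Package: cladePrimers
Title: Clade-Specific Degenerate qPCR Primer Design from Single-Copy Core Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Designs clade-specific degenerate (q)PCR primer pairs from the
    pan-genome of a target clade. Genes are clustered into families across
    genomes, single-copy core families are selected, their protein alignments
    are back-translated into codon alignments, and primer pairs are enumerated
    on the majority consensus under thermodynamic and structural constraints.
    Degeneracies (IUPAC ambiguity codes) are injected so each primer covers all
    observed variation at its binding site, pairs are filtered on degeneracy
    budgets, and off-target amplification potential is removed by in-silico PCR
    against the target gene catalogue and non-target sequences. Includes a
    nearest-neighbor melting temperature model, a synthetic pan-genome
    simulator with planted ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Genetics, Sequencing, Alignment, MultipleSequenceAlignment,
    SequenceMatching, qPCR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
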