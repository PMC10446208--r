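Package: varcontext
Title: Sequence-Context Annotation of Genomic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates the local sequence context of genomic variants read
    from VCF against a reference FASTA. Variants are split into biallelic
    records and normalized (parsimonious, left-aligned), after which the
    package computes indel breakpoint ambiguity (5'-aligned, 3'-aligned and
    3'-edge positions), in-duplicate status, flanking bases, HGVS DNA
    nomenclature, inter-variant distances, wildtype/mutated sequence
    extraction, custom BED annotation, and tandem-repeat regions discovered
    by a local sequence-context comparison algorithm with alignment and
    repeat scores. Ships a synthetic-fixture generator and brute-force
    oracles so the whole annotation path is testable on small inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
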