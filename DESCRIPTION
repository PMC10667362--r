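Package: nerdsig
Title: NER-Deficiency Calling from Somatic Indel Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls nucleotide-excision-repair (NER) deficiency and
    irofulven-responder candidacy from tumor whole-exome somatic variant
    calls. Implements stringent MuTect2-style somatic variant filtering,
    COSMIC ID-83 small insertion/deletion catalog construction with
    left-alignment, homopolymer, tandem-repeat and microhomology context
    classification, non-negative least-squares signature refitting to
    obtain absolute ID8 exposures, an ID8 threshold rule combined with a
    cell-line-calibrated PTGR1 expression gate, Fisher exact testing of
    ERCC-gene enrichment, and cohort summarization. A synthetic-cohort
    generator with a complete ground-truth ledger makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    S4Vectors,
    IRanges,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
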