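Package: xrlesion
Title: Mapping UV Lesions in Excision Repair Sequencing Reads via
    Cytosine Deamination Mismatches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pinpoints cyclobutane pyrimidine dimer (CPD) lesions inside
    excised nucleotide excision repair (NER) fragments sequenced by XR-seq,
    by exploiting the accelerated cytosine deamination of CPDs that leaves
    C>T (and tandem CC>TT) mismatches against the reference genome.
    Provides a ground-truth fragment simulator, an internal exact /
    one-mismatch read placer with SAM import, read-level quality filters
    (including the 3' TGG mispriming filter and data-driven read length
    ranges), mismatch-position lesion calling with a 5'-anchored background
    model, a revertant-sequence aligner for tandem CC>TT reads, incision
    site statistics (5'/3' contribution decomposition, HYV motif profiles,
    GC-normalised information content, incision coupling regression with a
    shuffle control), and nucleosome-dyad metaprofiles of cut-site
    distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
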